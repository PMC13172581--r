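# Synthetic scenarios: planted WT/KO domain architectures with ground-truth
# change labels, noisy replicate tracks, gene models and expression tables.

# Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Parameters of a synthetic domain-remodeling scenario
#'
#' Defaults emulate a mammalian LAD architecture at toy-genome scale:
#' domains with a median size of 0.5 Mb covering roughly a third of a
#' 2 x 10 Mb genome, remodeled by a handful of whole-domain gains/losses
#' and sub-domain edge edits.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param domain_median,domain_log_sd log-normal WT domain size (bp).
#' @param gap_median,gap_log_sd log-normal inter-domain gap size (bp).
#' @param n_gain,n_loss whole-domain gains/losses in the KO.
#' @param n_extend,n_retract edge extensions/retractions in the KO.
#' @param edit_median,edit_log_sd log-normal edit size (bp), also used for
#'   whole gained domains (remodeled domains are smaller than stable ones).
#' @param min_spacing minimum distance kept between any two edited or
#'   existing intervals (bp) so planted categories stay unambiguous;
#'   default 20 kb (two 10 kb bins).
#' @param min_keep minimum domain width that must survive a retraction (bp).
#' @param round_to quantization of all planted coordinates (bp, default
#'   10 kb): domain callers operate at bin resolution, so planted
#'   boundaries are placed on the same grid; set to 1 for bp-resolution
#'   scenarios.
#' @param seed root seed; all sub-streams derive from it.
#' @return A `ScenarioParams` list.
#' @export
scenario_params <- function(chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                            domain_median = 5e5, domain_log_sd = 0.45,
                            gap_median = 1e6, gap_log_sd = 0.45,
                            n_gain = 3, n_loss = 2,
                            n_extend = 3, n_retract = 3,
                            edit_median = 1.2e5, edit_log_sd = 0.35,
                            min_spacing = 2e4, min_keep = 6e4,
                            round_to = 1e4, seed = 1) {
  stopifnot(all(chrom_lengths > 0), domain_median > 0, gap_median > 0,
            n_gain >= 0, n_loss >= 0, n_extend >= 0, n_retract >= 0,
            edit_median > 0, min_spacing >= 0, min_keep > 0, round_to >= 1)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  structure(as.list(environment()), class = "ScenarioParams")
}

#' Simulate a WT/KO domain architecture with ground-truth labels
#'
#' Places non-overlapping WT domains chromosome by chromosome, then
#' derives the KO set by applying exactly the requested numbers of whole
#' gains, whole losses, edge extensions and edge retractions, each kept at
#' least `min_spacing` away from every other interval so the planted
#' category of every edited region is unambiguous. Deterministic given the
#' seed; fails loudly when the genome cannot host the requested edits.
#'
#' @param params a [scenario_params()] object.
#' @return A `SyntheticScenario`: list with `assembly`, `wt`, `ko`
#'   (`DomainSet`s), `truth` (`LADChangeMap`), `params`.
#' @export
simulate_scenario <- function(params = scenario_params()) {
  stopifnot(inherits(params, "ScenarioParams"))
  with_seed(params$seed, simulate_scenario_impl(params))
}

simulate_scenario_impl <- function(params) {
  asm <- genome_assembly(names(params$chrom_lengths), params$chrom_lengths)
  sp <- params$min_spacing
  rt <- params$round_to
  rnd <- function(x) pmax(round(x / rt) * rt, rt)
  # ---- WT placement ----
  wt <- list(chrom = character(), start = numeric(), end = numeric())
  for (ch in names(params$chrom_lengths)) {
    len <- params$chrom_lengths[[ch]]
    pos <- 0
    repeat {
      gap <- round(stats::rlnorm(1, log(params$gap_median), params$gap_log_sd))
      size <- round(stats::rlnorm(1, log(params$domain_median), params$domain_log_sd))
      gap <- rnd(max(gap, 2 * sp)); size <- rnd(max(size, params$min_keep))
      if (pos + gap + size + sp > len) break
      wt$chrom <- c(wt$chrom, ch)
      wt$start <- c(wt$start, pos + gap)
      wt$end <- c(wt$end, pos + gap + size)
      pos <- pos + gap + size
    }
  }
  nd <- length(wt$start)
  n_edited_domains <- params$n_loss + params$n_extend + params$n_retract
  if (nd < n_edited_domains) {
    stop("genome too small: ", nd, " WT domains cannot host ",
         n_edited_domains, " domain edits")
  }
  wt_df <- data.frame(chrom = wt$chrom, start = wt$start, end = wt$end,
                      stringsAsFactors = FALSE)
  # one edit per domain at most. Whole losses preferentially hit smaller
  # domains (small domains interact less stably with the lamina); the
  # remaining edited domains are drawn uniformly.
  w <- wt_df$end - wt_df$start
  loss_idx <- if (params$n_loss > 0) {
    sample.int(nd, params$n_loss, prob = 1 / w)
  } else integer()
  rest <- setdiff(seq_len(nd), loss_idx)
  idx <- rest[sample.int(length(rest), params$n_retract + params$n_extend)]
  retract_idx <- idx[seq_len(params$n_retract)]
  extend_idx <- idx[params$n_retract + seq_len(params$n_extend)]

  edit_size <- function(n) {
    rnd(pmax(round(stats::rlnorm(n, log(params$edit_median), params$edit_log_sd)),
             params$min_keep / 2))
  }

  truth <- list(LostLAD = wt_df[loss_idx, , drop = FALSE],
                LostEdge = NULL, GainedLAD = NULL, GainedEdge = NULL)
  ko_df <- wt_df

  # ---- retractions: shrink one end, keep >= min_keep ----
  if (length(retract_idx)) {
    le <- list()
    for (i in retract_idx) {
      w <- wt_df$end[i] - wt_df$start[i]
      r <- min(edit_size(1), w - params$min_keep)
      if (r < 1) stop("domain too small to retract (increase domain sizes)")
      if (stats::runif(1) < 0.5) {     # retract left end
        piece <- c(wt_df$start[i], wt_df$start[i] + r)
        ko_df$start[i] <- wt_df$start[i] + r
      } else {                          # retract right end
        piece <- c(wt_df$end[i] - r, wt_df$end[i])
        ko_df$end[i] <- wt_df$end[i] - r
      }
      le[[length(le) + 1L]] <- data.frame(chrom = wt_df$chrom[i],
                                          start = piece[1], end = piece[2])
    }
    truth$LostEdge <- do.call(rbind, le)
  }

  # ---- extensions: grow one end into the neighbouring gap ----
  if (length(extend_idx)) {
    ge <- list()
    for (i in extend_idx) {
      ch <- wt_df$chrom[i]
      # occupied space: WT footprints plus current KO intervals (so two
      # extensions can never collide in a shared gap), minus this domain
      occ <- rbind(wt_df[-i, , drop = FALSE], ko_df[-i, , drop = FALSE])
      occ <- occ[occ$chrom == ch, , drop = FALSE]
      left_lim <- max(c(0, occ$end[occ$end <= wt_df$start[i]]))
      right_lim <- min(c(params$chrom_lengths[[ch]],
                         occ$start[occ$start >= wt_df$end[i]]))
      e <- edit_size(1)
      room_left <- wt_df$start[i] - left_lim - sp
      room_right <- right_lim - wt_df$end[i] - sp
      side <- if (stats::runif(1) < 0.5) "left" else "right"
      room <- if (side == "left") room_left else room_right
      if (room < params$min_keep / 2) {       # try the other side
        side <- setdiff(c("left", "right"), side)
        room <- if (side == "left") room_left else room_right
      }
      if (room < params$min_keep / 2) {
        stop("no room to extend domain ", i, " (genome too crowded)")
      }
      e <- min(e, room)
      if (side == "left") {
        piece <- c(wt_df$start[i] - e, wt_df$start[i])
        ko_df$start[i] <- wt_df$start[i] - e
      } else {
        piece <- c(wt_df$end[i], wt_df$end[i] + e)
        ko_df$end[i] <- wt_df$end[i] + e
      }
      ge[[length(ge) + 1L]] <- data.frame(chrom = ch, start = piece[1],
                                          end = piece[2])
    }
    truth$GainedEdge <- do.call(rbind, ge)
  }

  # drop lost domains from KO
  if (length(loss_idx)) ko_df <- ko_df[-loss_idx, , drop = FALSE]

  # ---- whole gains: new domains clear of every WT/KO interval ----
  if (params$n_gain > 0) {
    occupied <- rbind(wt_df, ko_df)
    gains <- list()
    for (k in seq_len(params$n_gain)) {
      size <- edit_size(1)
      placed <- FALSE
      for (try in seq_len(500)) {
        ch <- sample(names(params$chrom_lengths), 1)
        len <- params$chrom_lengths[[ch]]
        if (len < size + 2 * sp) next
        s <- rnd(stats::runif(1, sp, len - size - sp))
        if (s + size + sp > len) next
        occ <- occupied[occupied$chrom == ch, , drop = FALSE]
        clear <- !any(s - sp < occ$end & occ$start < s + size + sp)
        if (clear) {
          gains[[k]] <- data.frame(chrom = ch, start = s, end = s + size)
          occupied <- rbind(occupied, gains[[k]])
          ko_df <- rbind(ko_df, gains[[k]])
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place whole gained domain (genome too crowded)")
    }
    truth$GainedLAD <- do.call(rbind, gains)
  }

  mk <- function(df, label) {
    if (is.null(df) || nrow(df) == 0L) return(domain_set(asm, label = label))
    domain_set(asm, df$chrom, df$start, df$end, label = label)
  }
  wt_set <- mk(wt_df, "WT")
  ko_set <- mk(ko_df, "KO")
  truth_map <- structure(list(
    cLAD = ds_intersect(wt_set, ko_set, "cLAD"),
    LostLAD = mk(truth$LostLAD, "LostLAD"),
    LostEdge = mk(truth$LostEdge, "LostEdge"),
    GainedLAD = mk(truth$GainedLAD, "GainedLAD"),
    GainedEdge = mk(truth$GainedEdge, "GainedEdge"),
    assembly = asm, ref_label = "WT", alt_label = "KO"),
    class = "LADChangeMap")
  structure(list(assembly = asm, wt = wt_set, ko = ko_set,
                 truth = truth_map, params = params),
            class = "SyntheticScenario")
}

#' @export
print.SyntheticScenario <- function(x, ...) {
  cat(sprintf("SyntheticScenario: %s genome, WT %.1f Mb in %d domains, KO %.1f Mb in %d domains\n",
              paste(names(x$params$chrom_lengths), collapse = "+"),
              coverage_bp(x$wt) / 1e6, length(x$wt),
              coverage_bp(x$ko) / 1e6, length(x$ko)))
  print(x$truth)
  invisible(x)
}

#' Apply a change map to a reference domain set
#'
#' Reconstructs the altered set as
#' `(ref \\ (LostLAD U LostEdge)) U GainedLAD U GainedEdge`. On a
#' consistent map this reproduces the altered condition exactly.
#'
#' @param ref reference `DomainSet`.
#' @param map an `LADChangeMap`.
#' @return The reconstructed altered `DomainSet`.
#' @export
apply_change_map <- function(ref, map) {
  kept <- ds_setdiff(ds_setdiff(ref, map$LostLAD), map$LostEdge)
  out <- ds_union(ds_union(kept, map$GainedLAD), map$GainedEdge)
  out$label <- map$alt_label
  out
}

#' Noise parameters for synthetic signal tracks
#'
#' Defaults give a log2-enrichment step of 1 between domain interior and
#' exterior with per-bin Gaussian noise of SD 0.5 (a signal-to-noise
#' ratio of 2) in 10 kb bins, two replicates per condition.
#'
#' @param mu_in,mu_out mean log2 enrichment inside/outside domains.
#' @param sigma per-bin noise SD (>= 0).
#' @param bin_size track bin size (bp).
#' @param n_replicates replicates per condition.
#' @param seed sub-stream seed.
#' @return A `NoiseParams` list.
#' @export
noise_params <- function(mu_in = 1, mu_out = 0, sigma = 0.5,
                         bin_size = 1e4, n_replicates = 2, seed = 101) {
  stopifnot(mu_in > mu_out, sigma >= 0, bin_size >= 1, n_replicates >= 1)
  structure(list(mu_in = mu_in, mu_out = mu_out, sigma = sigma,
                 bin_size = as.integer(bin_size),
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "NoiseParams")
}

#' Simulate replicate signal tracks for both conditions
#'
#' A bin's value is drawn from `Normal(mu_in, sigma)` when its midpoint
#' lies inside the condition's domain set and `Normal(mu_out, sigma)`
#' otherwise. Replicates use independent noise streams derived from the
#' seed by fixed offsets.
#'
#' @param scenario a `SyntheticScenario`.
#' @param noise a [noise_params()] object.
#' @return List with elements `WT` and `KO`, each a list of
#'   `BinnedTrack` replicates.
#' @export
simulate_signal_tracks <- function(scenario, noise = noise_params()) {
  conds <- list(WT = scenario$wt, KO = scenario$ko)
  lens <- GenomeInfoDb::seqlengths(scenario$assembly)
  out <- list()
  for (ci in seq_along(conds)) {
    cname <- names(conds)[ci]
    dom <- as.data.frame(conds[[cname]])
    reps <- list()
    for (r in seq_len(noise$n_replicates)) {
      reps[[r]] <- with_seed(noise$seed + 1000L * ci + r, {
        values <- lapply(names(lens), function(ch) {
          n <- ceiling(lens[[ch]] / noise$bin_size)
          mid <- (seq_len(n) - 1) * noise$bin_size +
            pmin(noise$bin_size, lens[[ch]] - (seq_len(n) - 1) * noise$bin_size) / 2
          d <- dom[dom$chrom == ch, , drop = FALSE]
          inside <- rep(FALSE, n)
          for (i in seq_len(nrow(d))) {
            inside[mid >= d$start[i] & mid < d$end[i]] <- TRUE
          }
          mu <- ifelse(inside, noise$mu_in, noise$mu_out)
          if (noise$sigma == 0) mu else stats::rnorm(n, mu, noise$sigma)
        })
        names(values) <- names(lens)
        binned_track(scenario$assembly, noise$bin_size, values)
      })
    }
    names(reps) <- paste0("rep", seq_along(reps))
    out[[cname]] <- reps
  }
  out
}

#' Simulate gene models on a scenario genome
#'
#' Genes get a random strand, 2-8 exons and UTRs flanking a CDS. A
#' requested fraction is placed overlapping gained regions of the truth
#' map (stratified placement: the realized fraction is exact); the rest
#' are placed clear of gained regions, optionally by at least
#' `min_gain_distance` bp. Transcripts never overlap each other.
#'
#' @param scenario a `SyntheticScenario`.
#' @param n_genes number of genes.
#' @param seed sub-stream seed.
#' @param frac_gained fraction of genes overlapping gained regions
#'   (default 0.3).
#' @param min_gain_distance minimum distance from non-gained genes to any
#'   gained region (bp, default 0).
#' @param length_median,length_log_sd log-normal transcript length (bp).
#' @return A `GeneSet`.
#' @export
simulate_genes <- function(scenario, n_genes = 200, seed = 202,
                           frac_gained = 0.15, min_gain_distance = 0,
                           length_median = 15000, length_log_sd = 0.5) {
  stopifnot(n_genes >= 0, frac_gained >= 0, frac_gained <= 1)
  asm <- scenario$assembly
  if (n_genes == 0L) {
    return(gene_set(asm, data.frame(gene_id = character(), chrom = character(),
                                    strand = character(), start = numeric(),
                                    end = numeric())[0, ], list()))
  }
  with_seed(seed, {
    lens <- GenomeInfoDb::seqlengths(asm)
    gained <- as.data.frame(ds_union(scenario$truth$GainedLAD,
                                     scenario$truth$GainedEdge))
    n_g <- round(frac_gained * n_genes)
    if (n_g > 0 && nrow(gained) == 0L) {
      stop("scenario has no gained regions but frac_gained > 0")
    }
    placed <- data.frame(chrom = character(), start = numeric(),
                         end = numeric())
    rows <- list(); exons <- list()
    overlaps_any <- function(ch, s, e, tab, margin = 0) {
      t2 <- tab[tab$chrom == ch, , drop = FALSE]
      nrow(t2) > 0 && any(s - margin < t2$end & t2$start < e + margin)
    }
    for (i in seq_len(n_genes)) {
      want_gained <- i <= n_g
      L <- max(2000, round(stats::rlnorm(1, log(length_median), length_log_sd)))
      ok <- FALSE
      for (try in seq_len(2000)) {
        if (want_gained) {
          gi <- sample.int(nrow(gained), 1)
          ch <- gained$chrom[gi]
          # anchor inside the gained interval guarantees >= 1 bp overlap
          anchor <- round(stats::runif(1, gained$start[gi], gained$end[gi] - 1))
          s <- max(0, anchor - round(stats::runif(1, 0, L - 1)))
          e <- s + L
        } else {
          ch <- sample(names(lens), 1)
          s <- round(stats::runif(1, 0, lens[[ch]] - L - 1))
          e <- s + L
        }
        if (e > lens[[ch]]) next
        if (overlaps_any(ch, s, e, placed)) next
        gene_overlaps_gained <- overlaps_any(ch, s, e, gained,
                                             if (want_gained) 0 else min_gain_distance)
        if (want_gained != gene_overlaps_gained) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place gene ", i, " after bounded retries")
      placed <- rbind(placed, data.frame(chrom = ch, start = s, end = e))
      strand <- sample(c("+", "-"), 1)
      ex <- make_exon_structure(s, e)
      rows[[i]] <- data.frame(
        gene_id = sprintf("gene%04d", i), chrom = ch, strand = strand,
        start = s, end = e, cds_start = ex$cds[1], cds_end = ex$cds[2],
        stringsAsFactors = FALSE)
      exons[[sprintf("gene%04d", i)]] <- ex$exons
    }
    gene_set(asm, do.call(rbind, rows), exons)
  })
}

# Random 2-8 exon layout within [s, e), CDS from mid-first to mid-last exon.
make_exon_structure <- function(s, e) {
  L <- e - s
  k <- sample(2:min(8, max(2, L %/% 400)), 1)
  nseg <- 2L * k - 1L                       # exon/intron alternation
  breaks <- sort(sample.int(L - 1L, nseg - 1L))
  bounds <- s + c(0, breaks, L)
  starts <- bounds[seq(1, nseg, by = 2)]
  ends <- bounds[seq(1, nseg, by = 2) + 1]
  cds <- c(floor((starts[1] + ends[1]) / 2),
           ceiling((starts[k] + ends[k]) / 2))
  if (cds[1] >= cds[2]) cds <- c(starts[1], ends[k])   # tiny genes
  list(exons = data.frame(start = starts, end = ends), cds = cds)
}

#' Effect parameters for synthetic expression tables
#'
#' @param p_effect probability that a gene overlapping a gained region is
#'   downregulated.
#' @param delta mean downregulation magnitude (log2 units).
#' @param effect_sd SD of the downregulation magnitude.
#' @param null_sd SD of null log2 fold changes.
#' @param fdr_affected,fdr_null uniform FDR generation bounds for
#'   affected / unaffected genes. The defaults make unaffected genes
#'   never significant; for null-calibration studies set
#'   `fdr_null = c(0, 1)` so chance DE arises independently of gain
#'   status.
#' @param base_log2_mean,base_log2_sd log2 baseline expression.
#' @param lad_repression baseline log2 reduction for genes inside WT
#'   domains (planted "genes in LADs are lowly expressed" signal).
#' @param seed sub-stream seed.
#' @return An `EffectParams` list.
#' @export
effect_params <- function(p_effect = 0.5, delta = 1, effect_sd = 0.25,
                          null_sd = 0.3, fdr_affected = c(0, 0.05),
                          fdr_null = c(0.05, 1), base_log2_mean = 5,
                          base_log2_sd = 1, lad_repression = 2,
                          seed = 303) {
  stopifnot(p_effect >= 0, p_effect <= 1, delta >= 0, effect_sd >= 0,
            null_sd >= 0, length(fdr_affected) == 2, length(fdr_null) == 2)
  structure(as.list(environment()), class = "EffectParams")
}

#' Simulate an expression table with a planted LAD-gain effect
#'
#' Genes whose body overlaps a gained region of the truth map are, with
#' probability `p_effect`, assigned `log2fc = -|Normal(delta, effect_sd)|`
#' and an FDR drawn from `fdr_affected`; all other genes draw a null
#' log2 fold change and an FDR from `fdr_null`. Baseline expression
#' (`base_mean`) is log-normal, reduced by `lad_repression` log2 units
#' for genes inside WT domains. Deterministic given the seed.
#'
#' @param genes a `GeneSet`.
#' @param scenario a `SyntheticScenario` (supplies the truth map and WT
#'   domains).
#' @param effect an [effect_params()] object.
#' @param gained optional precomputed logical vector (one per gene): does
#'   the gene body overlap a gained region? Saves recomputing the overlap
#'   when many tables are drawn on one gene set.
#' @return An `ExpressionTable` with columns `gene_id`, `log2fc`, `fdr`,
#'   `base_mean`, plus attributes `gained` and `affected`.
#' @export
simulate_expression <- function(genes, scenario, effect = effect_params(),
                                gained = NULL) {
  if (is.null(gained)) {
    gained <- assign_gene_domain_status(genes, scenario$truth)$gained
  }
  stopifnot(length(gained) == length(genes))
  g <- genes$genes
  wt_df <- as.data.frame(scenario$wt)
  in_wt <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(wt_df))) {
    in_wt <- in_wt | (g$chrom == wt_df$chrom[i] &
                        g$start < wt_df$end[i] & wt_df$start[i] < g$end)
  }
  n <- nrow(g)
  with_seed(effect$seed, {
    affected <- gained & (stats::runif(n) < effect$p_effect)
    log2fc <- stats::rnorm(n, 0, effect$null_sd)
    fdr <- stats::runif(n, effect$fdr_null[1], effect$fdr_null[2])
    if (any(affected)) {
      log2fc[affected] <- -abs(stats::rnorm(sum(affected), effect$delta,
                                            effect$effect_sd))
      fdr[affected] <- stats::runif(sum(affected), effect$fdr_affected[1],
                                    effect$fdr_affected[2])
    }
    base <- 2^stats::rnorm(n, effect$base_log2_mean -
                             effect$lad_repression * in_wt,
                           effect$base_log2_sd)
    tab <- expression_table(data.frame(
      gene_id = g$gene_id, log2fc = log2fc, fdr = fdr, base_mean = base,
      stringsAsFactors = FALSE))
    attr(tab, "gained") <- gained
    attr(tab, "affected") <- affected
    tab
  })
}

#' Write a full scenario to disk as standard text formats
#'
#' Emits chrom.sizes, WT/KO BED files, a truth BED (category in the name
#' column), per-condition replicate bedGraphs, a gene TSV and an
#' expression TSV.
#'
#' @param scenario a `SyntheticScenario`.
#' @param dir output directory (created if needed).
#' @param tracks optional output of [simulate_signal_tracks()].
#' @param genes optional `GeneSet`.
#' @param expression optional `ExpressionTable`.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir, tracks = NULL, genes = NULL,
                           expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lens <- GenomeInfoDb::seqlengths(scenario$assembly)
  utils::write.table(data.frame(names(lens), as.integer(lens)),
                     file.path(dir, "genome.chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  save_domains(scenario$wt, file.path(dir, "WT.bed"))
  save_domains(scenario$ko, file.path(dir, "KO.bed"))
  truth_rows <- do.call(rbind, lapply(change_categories(), function(cat_) {
    df <- as.data.frame(scenario$truth[[cat_]])
    if (nrow(df)) df$name <- cat_
    df
  }))
  utils::write.table(truth_rows, file.path(dir, "truth.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(tracks)) {
    for (cond in names(tracks)) {
      for (r in names(tracks[[cond]])) {
        save_track(tracks[[cond]][[r]],
                   file.path(dir, sprintf("%s.%s.bedgraph", cond, r)))
      }
    }
  }
  if (!is.null(genes)) save_genes(genes, file.path(dir, "genes.tsv"))
  if (!is.null(expression)) {
    utils::write.table(expression, file.path(dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
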