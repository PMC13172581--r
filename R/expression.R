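#' Classify differential expression
#'
#' A gene is `up` when `fdr < fdr_cut` and `log2fc >= log2(fc_cut)`,
#' `down` when `fdr < fdr_cut` and `log2fc <= -log2(fc_cut)`, otherwise
#' `ns`. The default rule (FDR < 0.05, fold change >= 1.2) takes the
#' table's fold changes as-is.
#'
#' @param expression an `ExpressionTable`.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param fc_cut fold-change threshold on the linear scale (default 1.2).
#' @return data.frame with `gene_id`, `log2fc`, `fdr`, `status` (factor
#'   `up`/`down`/`ns`); thresholds attached as attributes.
#' @export
classify_de <- function(expression, fdr_cut = 0.05, fc_cut = 1.2) {
  stopifnot(fdr_cut > 0, fdr_cut < 1, fc_cut >= 1)
  lcut <- log2(fc_cut)
  status <- rep("ns", nrow(expression))
  sig <- expression$fdr < fdr_cut
  status[sig & expression$log2fc >= lcut] <- "up"
  status[sig & expression$log2fc <= -lcut] <- "down"
  out <- data.frame(gene_id = expression$gene_id,
                    log2fc = expression$log2fc, fdr = expression$fdr,
                    status = factor(status, levels = c("up", "down", "ns")),
                    stringsAsFactors = FALSE)
  attr(out, "fdr_cut") <- fdr_cut
  attr(out, "fc_cut") <- fc_cut
  out
}

#' Attach LAD-change status to genes
#'
#' A gene is `gained` when its assignment region overlaps
#' `GainedLAD U GainedEdge` by at least `min_overlap` bp (analogously
#' `lost`); `both` when both hold, otherwise `none`. The assignment
#' region is the gene body, or the promoter window around the TSS with
#' `mode = "promoter"`.
#'
#' @param genes a `GeneSet`.
#' @param map an `LADChangeMap` on the same assembly.
#' @param mode `"body"` (default) or `"promoter"`.
#' @param min_overlap minimum overlap in bp (default 1); values in (0, 1)
#'   are interpreted as a fraction of the region length.
#' @param promoter_window length-2 bp window for `mode = "promoter"`.
#' @return data.frame with `gene_id`, `gained`, `lost` (logical) and
#'   `lad_status` (factor `gained`/`lost`/`both`/`none`).
#' @export
assign_gene_domain_status <- function(genes, map, mode = c("body", "promoter"),
                                      min_overlap = 1,
                                      promoter_window = c(3000, 3000)) {
  mode <- match.arg(mode)
  check_same_assembly(genes$assembly, map$cLAD)
  g <- genes$genes
  if (mode == "body") {
    s <- g$start; e <- g$end
  } else {
    tsspos <- ifelse(g$strand == "+", g$start, g$end - 1)
    s <- ifelse(g$strand == "+", tsspos - promoter_window[1],
                tsspos - promoter_window[2] + 1)
    e <- ifelse(g$strand == "+", tsspos + promoter_window[2],
                tsspos + promoter_window[1] + 1)
    lens <- GenomeInfoDb::seqlengths(genes$assembly)[g$chrom]
    s <- pmax(s, 0); e <- pmin(e, lens)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(g$chrom, levels = GenomeInfoDb::seqnames(genes$assembly)),
    ranges = IRanges::IRanges(start = s + 1L, end = as.integer(e)),
    seqinfo = genes$assembly)
  gain_set <- ds_union(map$GainedLAD, map$GainedEdge)$gr
  loss_set <- ds_union(map$LostLAD, map$LostEdge)$gr
  ov_bp <- function(set) {
    hits <- GenomicRanges::findOverlaps(gr, set)
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      gr[S4Vectors::queryHits(hits)], set[S4Vectors::subjectHits(hits)]))
    out <- numeric(length(gr))
    if (length(hits)) {
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  need <- if (min_overlap > 0 && min_overlap < 1) {
    min_overlap * (e - s)
  } else rep(min_overlap, length(gr))
  gained <- ov_bp(gain_set) >= need
  lost <- ov_bp(loss_set) >= need
  status <- ifelse(gained & lost, "both",
                   ifelse(gained, "gained", ifelse(lost, "lost", "none")))
  data.frame(gene_id = g$gene_id, gained = gained, lost = lost,
             lad_status = factor(status,
                                 levels = c("gained", "lost", "both", "none")),
             stringsAsFactors = FALSE)
}

#' Fisher's exact test for LAD-gain enrichment in downregulated genes
#'
#' Builds the 2x2 contingency table (rows: down-regulated vs
#' non-differentially-expressed genes; columns: LAD-gained vs not) and
#' computes the exact two-sided p-value by summing, over all tables with
#' the observed margins, the hypergeometric probabilities no larger than
#' the observed table's. Up-regulated genes are excluded by default,
#' mirroring the down-vs-ns construction; `include_up = TRUE` pools them
#' into the non-down row. The odds ratio is the cross-product `ad/bc`;
#' when any cell is zero a Haldane-Anscombe +0.5 correction is applied
#' and flagged.
#'
#' @param de output of [classify_de()].
#' @param lad_status output of [assign_gene_domain_status()] (matched by
#'   `gene_id`); genes with status `gained` or `both` count as gained.
#' @param include_up pool up-regulated genes into the comparison row
#'   (default `FALSE`: they are excluded).
#' @return An `EnrichmentResult`: list with `table` (2x2 counts),
#'   `odds_ratio`, `odds_ratio_corrected`, `p_value`, `corrected`
#'   (logical: zero-cell correction applied), `alpha` decision helper
#'   fields `enriched` (p < 0.05 and OR > 1).
#' @export
gain_enrichment_test <- function(de, lad_status, include_up = FALSE) {
  m <- merge(de, lad_status, by = "gene_id")
  if (nrow(m) == 0L) stop("no genes shared between DE table and LAD status")
  if (!include_up) m <- m[m$status != "up", , drop = FALSE]
  is_down <- m$status == "down"
  is_gained <- m$lad_status %in% c("gained", "both")
  a <- sum(is_down & is_gained); b <- sum(is_down & !is_gained)
  cc <- sum(!is_down & is_gained); d <- sum(!is_down & !is_gained)
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("down", "ns"), c("gained", "not_gained")))
  res <- fisher_2x2(a, b, cc, d)
  res$table <- tab
  res$enriched <- is.finite(res$p_value) && res$p_value < 0.05 &&
    (res$odds_ratio > 1 || is.infinite(res$odds_ratio))
  class(res) <- "EnrichmentResult"
  res
}

# Exact two-sided Fisher p for a 2x2 table, "probability <= observed"
# convention, plus cross-product odds ratio.
fisher_2x2 <- function(a, b, cc, d) {
  rs1 <- a + b; rs2 <- cc + d; cs1 <- a + cc; cs2 <- b + d
  n <- a + b + cc + d
  if (rs1 == 0L || rs2 == 0L || cs1 == 0L || cs2 == 0L) {
    warning("degenerate margin in 2x2 table; p = 1")
    return(list(odds_ratio = NA_real_, odds_ratio_corrected = NA_real_,
                p_value = 1, corrected = FALSE))
  }
  support <- max(0L, cs1 - rs2):min(rs1, cs1)
  probs <- stats::dhyper(support, rs1, rs2, cs1)
  p_obs <- stats::dhyper(a, rs1, rs2, cs1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * cc)   # may be Inf or NaN on zero cells
  corrected <- (a == 0 || b == 0 || cc == 0 || d == 0)
  or_c <- if (corrected) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else or
  if (is.nan(or)) or <- NA_real_
  list(odds_ratio = or, odds_ratio_corrected = or_c,
       p_value = p, corrected = corrected)
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat("LAD-gain enrichment (down vs ns), Fisher's exact test\n")
  print(x$table)
  or_txt <- if (x$corrected) {
    sprintf("%s (Haldane-Anscombe corrected: %.3f)",
            format(x$odds_ratio), x$odds_ratio_corrected)
  } else sprintf("%.3f", x$odds_ratio)
  cat(sprintf("odds ratio %s, two-sided p = %.4g%s\n", or_txt, x$p_value,
              if (x$enriched) "  [enriched at 0.05]" else ""))
  invisible(x)
}

#' Compare expression inside vs outside domains
#'
#' Splits genes by body overlap (>= 1 bp) with a domain set and compares
#' an expression column between the groups with a two-sided Wilcoxon
#' rank-sum test: exact enumeration of rank assignments (tie-aware) when
#' the smaller group has at most `exact_max` genes and the enumeration is
#' tractable, otherwise the tie-corrected normal approximation.
#'
#' @param genes a `GeneSet`.
#' @param lads a `DomainSet`.
#' @param expression an `ExpressionTable` covering the genes.
#' @param value column to compare: `"base_mean"` when present, else
#'   `"log2fc"` (or give a column name).
#' @param exact_max exact-test group-size bound (default 8).
#' @return List with `n_in`, `n_out`, `median_in`, `median_out`,
#'   `mean_in`, `mean_out`, `p_value`, `method`.
#' @export
expression_by_lad <- function(genes, lads, expression, value = NULL,
                              exact_max = 8) {
  check_same_assembly(genes$assembly, lads)
  if (is.null(value)) {
    value <- if ("base_mean" %in% names(expression)) "base_mean" else "log2fc"
  }
  g <- genes$genes
  gr <- GenomicRanges::GRanges(
    seqnames = factor(g$chrom, levels = GenomeInfoDb::seqnames(genes$assembly)),
    ranges = IRanges::IRanges(start = g$start + 1L, end = as.integer(g$end)),
    seqinfo = genes$assembly)
  in_lad <- GenomicRanges::countOverlaps(gr, lads$gr) > 0L
  vals <- expression[[value]][match(g$gene_id, expression$gene_id)]
  ok <- !is.na(vals)
  x <- vals[ok & in_lad]; y <- vals[ok & !in_lad]
  if (!length(x) || !length(y)) stop("one of the groups is empty")
  ws <- ranksum_test(x, y, exact_max = exact_max)
  list(n_in = length(x), n_out = length(y),
       median_in = stats::median(x), median_out = stats::median(y),
       mean_in = mean(x), mean_out = mean(y),
       p_value = ws$p_value, method = ws$method)
}

# Two-sided rank-sum test; exact tie-aware enumeration for small groups.
ranksum_test <- function(x, y, exact_max = 8, max_comb = 2e5) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  small <- min(n1, n2)
  if (small <= exact_max && choose(n, small) <= max_comb) {
    k <- if (n1 <= n2) n1 else n2
    combs <- utils::combn(n, k)
    w_all <- colSums(matrix(r[combs], nrow = k))
    mu_k <- k * (n + 1) / 2
    w_obs_k <- if (n1 <= n2) w_obs else sum(r[n1 + seq_len(n2)])
    p <- mean(abs(w_all - mu_k) >= abs(w_obs_k - mu_k) - 1e-9)
    return(list(p_value = p, method = "exact enumeration"))
  }
  # tie-corrected normal approximation on the rank-sum statistic
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(p_value = 1, method = "normal approximation"))
  z <- (w_obs - mu) / sqrt(sigma2)
  list(p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

#' Ordination of domain sets by binned genome coverage
#'
#' Rows are domain sets, columns are fixed-width genome bins, entries are
#' the fraction of each bin covered by the set. Columns are centred and
#' the matrix decomposed by singular values (principal components of the
#' coverage profiles).
#'
#' @param domain_sets list of >= 3 `DomainSet`s on one assembly.
#' @param bin_size genome bin width in bp (default 100 kb).
#' @return An `OrdinationResult`: list with `coords` (sets x components),
#'   `explained` (variance fractions, non-increasing), `distances`
#'   (pairwise Euclidean distances in component space), `labels`,
#'   `degenerate` (TRUE when all sets are identical).
#' @export
domain_overlap_pca <- function(domain_sets, bin_size = 1e5) {
  if (!is.list(domain_sets) || length(domain_sets) < 3) {
    stop("need at least 3 domain sets")
  }
  do.call(check_same_assembly, domain_sets)
  M <- domain_coverage_matrix(domain_sets, bin_size)
  labels <- vapply(domain_sets, function(d) d$label, "")
  Mc <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(Mc)
  ncomp <- min(nrow(M) - 1L, ncol(M))
  d <- sv$d[seq_len(ncomp)]
  coords <- sv$u[, seq_len(ncomp), drop = FALSE] %*% diag(d, ncomp)
  rownames(coords) <- labels
  tot <- sum(sv$d^2)
  degenerate <- tot < 1e-12
  explained <- if (degenerate) rep(0, ncomp) else d^2 / tot
  if (degenerate) {
    warning("all domain sets identical: zero-variance ordination")
    coords[] <- 0
  }
  dm <- as.matrix(stats::dist(coords))
  dimnames(dm) <- list(labels, labels)
  structure(list(coords = coords, explained = explained, distances = dm,
                 labels = labels, degenerate = degenerate,
                 bin_size = bin_size),
            class = "OrdinationResult")
}

# Rows = domain sets, columns = genome bins, entries = covered fraction.
domain_coverage_matrix <- function(domain_sets, bin_size) {
  asm <- domain_sets[[1]]$assembly
  lens <- GenomeInfoDb::seqlengths(asm)
  do.call(rbind, lapply(domain_sets, function(ds) {
    unlist(lapply(names(lens), function(ch) {
      n <- ceiling(lens[[ch]] / bin_size)
      cov <- numeric(n)
      df <- as.data.frame(ds)
      df <- df[df$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(df))) {
        b0 <- df$start[i] %/% bin_size; b1 <- (df$end[i] - 1) %/% bin_size
        for (b in b0:b1) {
          lo <- max(df$start[i], b * bin_size)
          hi <- min(df$end[i], (b + 1) * bin_size, lens[[ch]])
          cov[b + 1] <- cov[b + 1] + (hi - lo)
        }
      }
      widths <- pmin(seq_len(n) * bin_size, lens[[ch]]) -
        (seq_len(n) - 1) * bin_size
      cov / widths
    }), use.names = FALSE)
  }))
}

#' @export
print.OrdinationResult <- function(x, ...) {
  cat(sprintf("Domain-set ordination: %d sets, %d bp bins%s\n",
              length(x$labels), x$bin_size,
              if (x$degenerate) " (degenerate)" else ""))
  cat("explained variance:", paste(sprintf("%.3f", x$explained), collapse = " "),
      "\n")
  print(round(x$coords, 4))
  invisible(x)
}
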