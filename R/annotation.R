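#' Assign intervals to gene features
#'
#' Each interval is represented by its midpoint (`floor((start+end)/2)`,
#' 0-based) and assigned exactly one feature with the precedence
#' `Promoter > 5'UTR > 3'UTR > Exon > Intron > Downstream >
#' DistalIntergenic`:
#' \itemize{
#'   \item Promoter: within the promoter window around any TSS, in the
#'     gene's 5'-to-3' frame (signed distance in `[-upstream, downstream)`).
#'   \item 5'/3'UTR: within exonic sequence outside the CDS (genes without
#'     CDS coordinates contribute no UTRs).
#'   \item Exon / Intron: within an exon / within the transcript span but
#'     not an exon.
#'   \item Downstream: at most `downstream_bp` past the transcript 3' end.
#'   \item DistalIntergenic: anything else.
#' }
#' The signed distance to the nearest TSS (negative = upstream in the
#' gene's frame) is reported for every interval; equidistant TSS ties
#' break to the lexicographically smaller gene id.
#'
#' @param intervals a `DomainSet` (or any peak set as one).
#' @param genes a `GeneSet` (non-empty).
#' @param promoter_window length-2 numeric: bp upstream and downstream of
#'   the TSS counted as promoter (default `c(3000, 3000)`).
#' @param downstream_bp bp past the 3' end counted as Downstream
#'   (default 3000).
#' @return data.frame with `chrom`, `start`, `end`, `midpoint`, `feature`
#'   (factor over the seven classes), `nearest_gene`, `tss_distance`.
#' @export
annotate_intervals <- function(intervals, genes,
                               promoter_window = c(3000, 3000),
                               downstream_bp = 3000) {
  if (length(genes) == 0L) stop("empty gene set (distance undefined)")
  check_same_assembly(intervals, genes$assembly)
  iv <- as.data.frame(intervals)
  if (nrow(iv) == 0L) stop("no intervals to annotate")
  iv$midpoint <- floor((iv$start + iv$end) / 2)
  g <- genes$genes
  tss <- gene_tss(genes)
  feats <- feature_intervals(genes, promoter_window, downstream_bp)
  res_feature <- character(nrow(iv))
  res_gene <- character(nrow(iv))
  res_dist <- numeric(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    m <- iv$midpoint[i]; ch <- iv$chrom[i]
    # nearest TSS, signed in the gene's 5'->3' frame
    cand <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(cand) == 0L) {
      # no gene on this chromosome: distance undefined
      res_gene[i] <- NA_character_
      res_dist[i] <- NA_real_
    } else {
      d_signed <- ifelse(cand$strand == "+", m - cand$tss, cand$tss - m)
      ord <- order(abs(d_signed), cand$gene_id)
      res_gene[i] <- cand$gene_id[ord[1]]
      res_dist[i] <- d_signed[ord[1]]
    }
    res_feature[i] <- assign_feature(ch, m, feats)
  }
  out <- cbind(iv, data.frame(
    feature = factor(res_feature, levels = feature_classes()),
    nearest_gene = res_gene, tss_distance = res_dist,
    stringsAsFactors = FALSE))
  out
}

#' The seven feature classes, in precedence order
#' @return Character vector.
#' @export
feature_classes <- function() {
  c("Promoter", "5'UTR", "3'UTR", "Exon", "Intron", "Downstream",
    "DistalIntergenic")
}

# Precompute per-class interval tables (0-based half-open, per chromosome).
feature_intervals <- function(genes, promoter_window, downstream_bp) {
  g <- genes$genes
  up <- promoter_window[1]; dn <- promoter_window[2]
  plus <- g$strand == "+"
  tsspos <- ifelse(plus, g$start, g$end - 1)
  prom <- data.frame(
    chrom = g$chrom,
    start = ifelse(plus, tsspos - up, tsspos - dn + 1),
    end = ifelse(plus, tsspos + dn, tsspos + up + 1))
  down <- data.frame(
    chrom = g$chrom,
    start = ifelse(plus, g$end, g$start - downstream_bp),
    end = ifelse(plus, g$end + downstream_bp, g$start))
  utr5 <- list(); utr3 <- list(); exon <- list(); span <- list()
  for (i in seq_len(nrow(g))) {
    ex <- genes$exons[[g$gene_id[i]]]
    exon[[i]] <- data.frame(chrom = g$chrom[i], start = ex$start, end = ex$end)
    span[[i]] <- data.frame(chrom = g$chrom[i], start = g$start[i], end = g$end[i])
    if (!is.na(g$cds_start[i])) {
      left <- clip_intervals(ex, -Inf, g$cds_start[i])
      right <- clip_intervals(ex, g$cds_end[i], Inf)
      if (plus[i]) { u5 <- left; u3 <- right } else { u5 <- right; u3 <- left }
      if (nrow(u5)) utr5[[length(utr5) + 1L]] <- data.frame(chrom = g$chrom[i], u5)
      if (nrow(u3)) utr3[[length(utr3) + 1L]] <- data.frame(chrom = g$chrom[i], u3)
    }
  }
  list(Promoter = prom,
       `5'UTR` = do.call(rbind, utr5),
       `3'UTR` = do.call(rbind, utr3),
       Exon = do.call(rbind, exon),
       Span = do.call(rbind, span),
       Downstream = down)
}

clip_intervals <- function(iv, lo, hi) {
  s <- pmax(iv$start, lo); e <- pmin(iv$end, hi)
  keep <- s < e
  data.frame(start = s[keep], end = e[keep])
}

point_in <- function(ch, m, tab) {
  if (is.null(tab) || nrow(tab) == 0L) return(FALSE)
  any(tab$chrom == ch & tab$start <= m & m < tab$end)
}

assign_feature <- function(ch, m, feats) {
  if (point_in(ch, m, feats$Promoter)) return("Promoter")
  if (point_in(ch, m, feats$`5'UTR`)) return("5'UTR")
  if (point_in(ch, m, feats$`3'UTR`)) return("3'UTR")
  if (point_in(ch, m, feats$Exon)) return("Exon")
  if (point_in(ch, m, feats$Span)) return("Intron")
  if (point_in(ch, m, feats$Downstream)) return("Downstream")
  "DistalIntergenic"
}

#' Feature distribution of annotated intervals
#'
#' @param assignments output of [annotate_intervals()].
#' @return A `FeatureDistribution`: data.frame with `feature`, `count`,
#'   `percent` (summing to 100), plus attribute `total`.
#' @export
feature_distribution <- function(assignments) {
  if (nrow(assignments) == 0L) stop("no assignments")
  counts <- table(assignments$feature)
  out <- data.frame(feature = names(counts), count = as.integer(counts),
                    percent = as.numeric(counts) / nrow(assignments) * 100,
                    stringsAsFactors = FALSE)
  attr(out, "total") <- nrow(assignments)
  class(out) <- c("FeatureDistribution", "data.frame")
  out
}

#' Per-feature percentage change between two distributions
#'
#' @param ref,alt `FeatureDistribution`s over the same feature vocabulary.
#' @return data.frame with `feature`, `ref_percent`, `alt_percent`,
#'   `delta` (alt minus ref, percentage points), sorted by `|delta|`
#'   descending.
#' @export
compare_feature_distributions <- function(ref, alt) {
  if (!setequal(ref$feature, alt$feature)) stop("feature vocabulary mismatch")
  m <- match(ref$feature, alt$feature)
  out <- data.frame(feature = ref$feature,
                    ref_percent = ref$percent,
                    alt_percent = alt$percent[m],
                    delta = alt$percent[m] - ref$percent,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$delta)), , drop = FALSE]
}

#' Signed distance-to-TSS distribution
#'
#' Bins interval midpoints by signed distance to the nearest TSS in the
#' gene's 5'-to-3' frame (negative = upstream). A distance of exactly 0
#' falls in the first downstream bin.
#'
#' @param intervals a `DomainSet`.
#' @param genes a `GeneSet`.
#' @param breaks_kb upper bin edges in kb (default
#'   `c(1, 3, 5, 10, 100, Inf)` giving 0-1, 1-3, 3-5, 5-10, 10-100 and
#'   >100 kb bins on each side).
#' @return data.frame with `side` (`upstream`/`downstream`), `bin` (label),
#'   `count`, `fraction` (all rows summing to 1).
#' @export
tss_distance_distribution <- function(intervals, genes,
                                      breaks_kb = c(1, 3, 5, 10, 100, Inf)) {
  ann <- annotate_intervals(intervals, genes)
  d <- ann$tss_distance
  edges <- c(0, breaks_kb * 1000)
  labs <- paste0(edges[-length(edges)] / 1000, "-", breaks_kb, " kb")
  labs[length(labs)] <- paste0(">", edges[length(edges) - 1] / 1000, " kb")
  if (anyNA(d)) stop("TSS distance undefined for some intervals (chromosome without genes)")
  side <- ifelse(d >= 0, "downstream", "upstream")
  # bins are (lo, hi] with 0 included in the first downstream bin
  bin <- cut(abs(d), breaks = edges, labels = labs, right = TRUE,
             include.lowest = TRUE)
  grid <- expand.grid(side = c("upstream", "downstream"), bin = labs,
                      stringsAsFactors = FALSE)
  counts <- mapply(function(s, b) sum(side == s & bin == b),
                   grid$side, grid$bin)
  data.frame(side = grid$side, bin = grid$bin, count = as.integer(counts),
             fraction = counts / length(d), stringsAsFactors = FALSE)
}
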