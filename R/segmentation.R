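#' Caller parameters for broad-domain segmentation
#'
#' @param threshold absolute signal threshold; bins at or above it are
#'   domain-state. Exactly one of `threshold`/`quantile` must be given.
#' @param quantile genome-wide quantile (in (0,1)) of the non-missing bin
#'   values used as the threshold. Default `0.75`.
#' @param gap_bins maximum run of sub-threshold (or missing) bins bridged
#'   inside a domain. Default 1.
#' @param min_bins minimum domain length in bins; shorter runs are
#'   dropped. Default 3.
#' @return A `CallerParams` list.
#' @export
caller_params <- function(threshold = NULL, quantile = if (is.null(threshold)) 0.75,
                          gap_bins = 1, min_bins = 3) {
  if (is.null(threshold) == is.null(quantile)) {
    stop("give exactly one of 'threshold' or 'quantile'")
  }
  if (!is.null(quantile) && (quantile <= 0 || quantile >= 1)) {
    stop("quantile must lie in (0, 1)")
  }
  if (gap_bins < 0 || min_bins < 1) stop("gap_bins >= 0 and min_bins >= 1 required")
  structure(list(threshold = threshold, quantile = quantile,
                 gap_bins = as.integer(gap_bins), min_bins = as.integer(min_bins)),
            class = "CallerParams")
}

#' Call broad domains from a binned enrichment track
#'
#' A deliberately simple two-state segmentation standing in for dedicated
#' broad-domain callers: bins at or above a threshold (absolute, or a
#' genome-wide quantile of the non-missing values) form domain runs; runs
#' separated by at most `gap_bins` sub-threshold bins are joined; joined
#' runs shorter than `min_bins` are dropped. Missing bins count as
#' sub-threshold for run breaking but never contribute to the quantile.
#' Output intervals are clipped to chromosome ends.
#'
#' @param track a `BinnedTrack`.
#' @param params a [caller_params()] object.
#' @param label label for the resulting `DomainSet`.
#' @return A `DomainSet`.
#' @export
call_domains <- function(track, params = caller_params(), label = "called") {
  all_vals <- unlist(track$values, use.names = FALSE)
  if (all(is.na(all_vals))) stop("all track bins are missing")
  thr <- params$threshold
  if (is.null(thr)) {
    vals <- all_vals[!is.na(all_vals)]
    thr <- stats::quantile(vals, params$quantile, names = FALSE)
    if (min(vals) == max(vals)) {
      warning("constant track: quantile threshold is degenerate")
    }
  }
  lens <- GenomeInfoDb::seqlengths(track$assembly)
  bs <- track$bin_size
  chrom <- character(); start <- numeric(); end <- numeric()
  for (ch in names(lens)) {
    v <- track$values[[ch]]
    b <- !is.na(v) & v >= thr
    runs <- segment_runs(b, params$gap_bins, params$min_bins)
    if (nrow(runs)) {
      chrom <- c(chrom, rep(ch, nrow(runs)))
      start <- c(start, (runs$first - 1) * bs)
      end <- c(end, pmin(runs$last * bs, lens[[ch]]))
    }
  }
  domain_set(track$assembly, chrom, start, end, label = label)
}

# Runs of TRUE in a logical vector, with gap bridging then min-length
# filtering. Returns data.frame(first, last) of 1-based bin indices.
segment_runs <- function(b, gap_bins, min_bins) {
  r <- rle(b)
  if (gap_bins > 0 && length(r$lengths) > 2) {
    # internal FALSE runs no longer than the gap tolerance, flanked by TRUE
    idx <- which(!r$values & r$lengths <= gap_bins)
    idx <- idx[idx > 1 & idx < length(r$lengths)]
    if (length(idx)) {
      r$values[idx] <- TRUE
      r <- rle(inverse.rle(r))
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bins
  data.frame(first = starts[keep], last = ends[keep])
}

#' Merge replicate domain calls
#'
#' Base-level combination of two replicate calls into a condition-level
#' set. The default is the union (overlapping or book-ended intervals
#' coalesced); `mode = "intersection"` keeps only bases supported by both
#' replicates, for sensitivity analysis.
#'
#' @param rep1,rep2 `DomainSet`s on the same assembly.
#' @param mode `"union"` (default) or `"intersection"`.
#' @param label label for the merged set.
#' @return A `DomainSet`.
#' @export
merge_replicates <- function(rep1, rep2, mode = c("union", "intersection"),
                             label = NULL) {
  mode <- match.arg(mode)
  if (is.null(label)) label <- paste0(rep1$label, "+", rep2$label)
  if (mode == "union") ds_union(rep1, rep2, label) else ds_intersect(rep1, rep2, label)
}

#' Constitutive domains across conditions
#'
#' Base-level intersection of two or more domain sets: the regions called
#' in every condition (e.g. constitutive LADs).
#'
#' @param sets list of `DomainSet`s (>= 2) on one assembly.
#' @param label label for the result.
#' @return A `DomainSet`.
#' @export
consensus_intersection <- function(sets, label = "constitutive") {
  if (!is.list(sets) || length(sets) < 2) stop("need at least 2 domain sets")
  do.call(check_same_assembly, sets)
  out <- sets[[1]]
  for (s in sets[-1]) out <- ds_intersect(out, s)
  out$label <- label
  out
}

#' Three-set Venn coverage
#'
#' Partitions the union of three domain sets into the seven exclusive
#' Venn regions and reports each region's base-level coverage.
#'
#' @param a,b,c `DomainSet`s on one assembly.
#' @param mb_digits decimals for the Mb column (default 1).
#' @return A `VennCoverage`: data.frame with `region`
#'   (`A.only`,`B.only`,`C.only`,`AB`,`AC`,`BC`,`ABC`), `bp`, `mb`, plus
#'   attributes `labels` and `union_bp`.
#' @export
venn_coverage <- function(a, b, c, mb_digits = 1) {
  check_same_assembly(a, b, c)
  ab <- ds_intersect(a, b); ac <- ds_intersect(a, c); bc <- ds_intersect(b, c)
  abc <- ds_intersect(ab, c)
  regions <- list(
    A.only = ds_setdiff(ds_setdiff(a, b), c),
    B.only = ds_setdiff(ds_setdiff(b, a), c),
    C.only = ds_setdiff(ds_setdiff(c, a), b),
    AB = ds_setdiff(ab, c),
    AC = ds_setdiff(ac, b),
    BC = ds_setdiff(bc, a),
    ABC = abc)
  bp <- vapply(regions, coverage_bp, 1.0)
  out <- data.frame(region = names(regions), bp = unname(bp),
                    mb = bp_to_mb(unname(bp), mb_digits),
                    stringsAsFactors = FALSE)
  attr(out, "labels") <- c(A = a$label, B = b$label, C = c$label)
  attr(out, "union_bp") <- coverage_bp(ds_union(ds_union(a, b), c))
  class(out) <- c("VennCoverage", "data.frame")
  out
}

#' @export
print.VennCoverage <- function(x, ...) {
  lb <- attr(x, "labels")
  cat(sprintf("Venn coverage (A=%s, B=%s, C=%s), union %.1f Mb\n",
              lb["A"], lb["B"], lb["C"], attr(x, "union_bp") / 1e6))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Average replicate tracks bin-wise
#'
#' The signal-level analogue of merging replicate alignments before
#' domain calling: each bin's value is the mean of the non-missing
#' replicate values (missing only where all replicates are missing).
#'
#' @param tracks list of `BinnedTrack`s on one assembly with equal bin
#'   size.
#' @return A `BinnedTrack`.
#' @export
average_tracks <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  do.call(check_same_assembly, tracks)
  bs <- unique(vapply(tracks, function(t) t$bin_size, 1L))
  if (length(bs) != 1L) stop("bin sizes differ between replicates")
  ref <- tracks[[1]]
  vals <- lapply(names(ref$values), function(ch) {
    m <- do.call(cbind, lapply(tracks, function(t) t$values[[ch]]))
    v <- rowMeans(m, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  })
  names(vals) <- names(ref$values)
  binned_track(ref$assembly, bs, vals)
}

#' Call broad domains with a two-state Gaussian hidden Markov model
#'
#' The default segmentation of the pipeline: bin values are modelled as a
#' two-component Gaussian mixture (background vs domain) whose parameters
#' are estimated by EM on the genome-wide value distribution; domain/
#' background state sequences are then decoded per chromosome by the
#' Viterbi algorithm with a symmetric transition matrix. The
#' self-transition probability encodes the expected domain scale
#' (0.98 at 10 kb bins corresponds to mean run lengths of ~0.5 Mb, the
#' typical size of mammalian lamina-associated domains). Missing bins
#' carry no emission evidence and are bridged by the state prior.
#'
#' @param track a `BinnedTrack`.
#' @param self_transition probability of staying in the current state per
#'   bin (in (0,1); default 0.98).
#' @param min_bins minimum domain length in bins (default 3).
#' @param label label for the resulting set.
#' @return A `DomainSet`.
#' @export
call_domains_hmm <- function(track, self_transition = 0.98, min_bins = 3,
                             label = "called") {
  stopifnot(self_transition > 0, self_transition < 1, min_bins >= 1)
  all_vals <- unlist(track$values, use.names = FALSE)
  if (all(is.na(all_vals))) stop("all track bins are missing")
  fit <- gaussian_mixture2(all_vals)
  if (abs(fit$mu[2] - fit$mu[1]) < 1e-9) {
    warning("constant track: no separable domain state; empty set returned")
    return(domain_set(track$assembly, label = label))
  }
  lens <- GenomeInfoDb::seqlengths(track$assembly)
  bs <- track$bin_size
  chrom <- character(); start <- numeric(); end <- numeric()
  for (ch in names(lens)) {
    state <- viterbi_two_state(track$values[[ch]], fit, self_transition)
    r <- rle(state)
    ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1L
    keep <- r$values & r$lengths >= min_bins
    if (any(keep)) {
      chrom <- c(chrom, rep(ch, sum(keep)))
      start <- c(start, (starts_i[keep] - 1) * bs)
      end <- c(end, pmin(ends_i[keep] * bs, lens[[ch]]))
    }
  }
  domain_set(track$assembly, chrom, start, end, label = label)
}

# EM fit of a two-component Gaussian mixture to the non-missing values;
# component 2 is the higher-mean (domain) state. Deterministic: fixed
# quantile initialization.
gaussian_mixture2 <- function(v, max_iter = 200, tol = 1e-8) {
  v <- v[!is.na(v)]
  mu <- stats::quantile(v, c(0.15, 0.85), names = FALSE)
  s <- rep(max(stats::sd(v) / 2, 1e-9), 2)
  w <- c(0.5, 0.5)
  for (i in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(v, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(v, mu[2], s[2])
    g <- d2 / (d1 + d2)
    g[!is.finite(g)] <- 0.5
    w2 <- mean(g)
    mu_new <- c(sum((1 - g) * v) / sum(1 - g), sum(g * v) / sum(g))
    s_new <- pmax(c(sqrt(sum((1 - g) * (v - mu_new[1])^2) / sum(1 - g)),
                    sqrt(sum(g * (v - mu_new[2])^2) / sum(g))), 1e-9)
    done <- max(abs(mu_new - mu)) < tol
    mu <- mu_new; s <- s_new; w <- c(1 - w2, w2)
    if (done) break
  }
  if (mu[2] < mu[1]) { mu <- rev(mu); s <- rev(s); w <- rev(w) }
  list(mu = mu, s = s, w = pmax(pmin(w, 1 - 1e-12), 1e-12))
}

# Viterbi decoding of the domain state (TRUE = high-mean component).
viterbi_two_state <- function(v, fit, self) {
  n <- length(v)
  lt <- log(matrix(c(self, 1 - self, 1 - self, self), 2))
  dp <- matrix(-Inf, 2, n); bt <- matrix(1L, 2, n)
  emis <- function(x) {
    if (is.na(x)) c(0, 0) else stats::dnorm(x, fit$mu, fit$s, log = TRUE)
  }
  dp[, 1] <- log(fit$w) + emis(v[1])
  if (n > 1) for (t in 2:n) {
    ev <- emis(v[t])
    for (j in 1:2) {
      cand <- dp[, t - 1] + lt[, j]
      bt[j, t] <- which.max(cand)
      dp[j, t] <- cand[bt[j, t]] + ev[j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(dp[, n])
  if (n > 1) for (t in n:2) path[t - 1] <- bt[path[t], t]
  path == 2L
}
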