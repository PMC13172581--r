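#' Five-category classification of domain change
#'
#' Partitions the difference between a reference and an altered domain set
#' into the five change categories used for LAD remodeling:
#' \describe{
#'   \item{cLAD}{bases in both sets (common LAD).}
#'   \item{GainedLAD}{maximal piece of `alt - ref` whose containing
#'     altered domain has no overlap at all with the reference (a whole
#'     new domain).}
#'   \item{GainedEdge}{piece of `alt - ref` whose containing altered
#'     domain does overlap the reference (boundary extension, including
#'     gap-bridging growth and filled internal holes).}
#'   \item{LostLAD}{maximal piece of `ref - alt` whose containing
#'     reference domain has no overlap with the altered set (a whole
#'     domain disappeared).}
#'   \item{LostEdge}{piece of `ref - alt` whose containing reference
#'     domain persists in the altered set (boundary retraction or an
#'     internal hole).}
#' }
#' Genome outside `ref` and `alt` is inter-LAD and left implicit. The
#' whole-vs-edge decision is containment-based and parameter-free.
#'
#' @param ref,alt `DomainSet`s on one assembly (reference and altered
#'   condition).
#' @param verbose if `TRUE`, edge pieces additionally carry a `side`
#'   annotation (`left`, `right`, `internal`) distinguishing terminal
#'   flanks from internal holes, returned in the `edge_sides` element.
#' @return An `LADChangeMap`: list with one `DomainSet` per category
#'   (`cLAD`, `LostLAD`, `LostEdge`, `GainedLAD`, `GainedEdge`), the
#'   assembly, labels, and optionally `edge_sides`.
#' @export
classify_changes <- function(ref, alt, verbose = FALSE) {
  check_same_assembly(ref, alt)
  # book-ended intervals are one domain semantically; normalize first
  ref <- domain_set_from_granges(ref$gr, ref$label)
  alt <- domain_set_from_granges(alt$gr, alt$label)
  clad <- ds_intersect(ref, alt, "cLAD")
  gained <- split_change_pieces(alt, ref, want_side = verbose)
  lost <- split_change_pieces(ref, alt, want_side = verbose)
  map <- structure(list(
    cLAD = clad,
    LostLAD = new_domain_set(lost$whole, "LostLAD"),
    LostEdge = new_domain_set(lost$edge, "LostEdge"),
    GainedLAD = new_domain_set(gained$whole, "GainedLAD"),
    GainedEdge = new_domain_set(gained$edge, "GainedEdge"),
    assembly = ref$assembly,
    ref_label = ref$label, alt_label = alt$label),
    class = "LADChangeMap")
  if (verbose) {
    map$edge_sides <- list(GainedEdge = gained$side, LostEdge = lost$side)
  }
  map
}

# Pieces of `a - b`, split by whether the containing domain of `a`
# overlaps `b` at all (edge) or not (whole). The per-piece side labels
# (left/right flank vs internal hole) are only computed on request.
split_change_pieces <- function(a, b, want_side = FALSE) {
  pieces <- GenomicRanges::setdiff(a$gr, b$gr)
  if (!length(pieces)) {
    empty <- pieces
    return(list(whole = empty, edge = empty, side = character()))
  }
  hit <- GenomicRanges::findOverlaps(pieces, a$gr)
  stopifnot(length(hit) == length(pieces))   # each piece lies in one domain
  parent <- a$gr[S4Vectors::subjectHits(hit)]
  parent_touches_b <- GenomicRanges::countOverlaps(parent, b$gr) > 0L
  edge <- pieces[parent_touches_b]
  edge_parent <- parent[parent_touches_b]
  side <- character(length(edge))
  if (want_side && length(edge)) {
    # retained part of the parent domain in the other condition
    kept <- GenomicRanges::intersect(edge_parent, b$gr)
    for (i in seq_along(edge)) {
      k <- kept[S4Vectors::queryHits(
        GenomicRanges::findOverlaps(kept, edge_parent[i], type = "within"))]
      left_kept <- any(GenomicRanges::start(k) < GenomicRanges::start(edge[i]))
      right_kept <- any(GenomicRanges::end(k) > GenomicRanges::end(edge[i]))
      side[i] <- if (left_kept && right_kept) "internal"
                 else if (left_kept) "right" else "left"
    }
  }
  list(whole = pieces[!parent_touches_b], edge = edge, side = side)
}

#' @export
print.LADChangeMap <- function(x, ...) {
  cat(sprintf("LADChangeMap: %s -> %s\n", x$ref_label, x$alt_label))
  for (cat_ in change_categories()) {
    cat(sprintf("  %-10s %5d interval(s) %10.3f Mb\n", cat_,
                length(x[[cat_]]$gr), coverage_bp(x[[cat_]]) / 1e6))
  }
  invisible(x)
}

#' The five change-category labels
#' @return Character vector of category names.
#' @export
change_categories <- function() {
  c("cLAD", "LostLAD", "LostEdge", "GainedLAD", "GainedEdge")
}

#' Brute-force change classification (test oracle)
#'
#' Independent implementation of [classify_changes()] that labels every
#' genome position (at a given resolution) on its own and then coalesces
#' runs of equal labels. Quadratic in genome size; intended for small
#' genomes as an oracle.
#'
#' @param ref,alt `DomainSet`s on one assembly.
#' @param resolution step in bp at which positions are enumerated
#'   (default 1; coordinates must be multiples of it for exactness).
#' @param max_positions safety cap on enumerated positions per chromosome.
#' @return An `LADChangeMap`.
#' @export
classify_changes_bruteforce <- function(ref, alt, resolution = 1,
                                        max_positions = 5e6) {
  check_same_assembly(ref, alt)
  lens <- GenomeInfoDb::seqlengths(ref$assembly)
  acc <- list()
  for (cat_ in change_categories()) {
    acc[[cat_]] <- list(chrom = character(), start = numeric(), end = numeric())
  }
  for (ch in names(lens)) {
    npos <- ceiling(lens[[ch]] / resolution)
    if (npos > max_positions) stop("genome too large for brute-force enumeration")
    pos <- (seq_len(npos) - 1) * resolution      # 0-based positions sampled
    in_ref <- positions_in(pos, ref, ch)
    in_alt <- positions_in(pos, alt, ch)
    # which domain covers each position, and does that domain touch the
    # other set anywhere (computed positionally, independent of overlap code)
    ref_id <- covering_domain_id(pos, ref, ch)
    alt_id <- covering_domain_id(pos, alt, ch)
    ref_dom_touches_alt <- tapply(in_alt[in_ref], ref_id[in_ref], any)
    alt_dom_touches_ref <- tapply(in_ref[in_alt], alt_id[in_alt], any)
    lab <- rep("iLAD", npos)
    lab[in_ref & in_alt] <- "cLAD"
    only_ref <- in_ref & !in_alt
    only_alt <- in_alt & !in_ref
    if (any(only_ref)) {
      touches <- ref_dom_touches_alt[as.character(ref_id[only_ref])]
      lab[only_ref] <- ifelse(touches, "LostEdge", "LostLAD")
    }
    if (any(only_alt)) {
      touches <- alt_dom_touches_ref[as.character(alt_id[only_alt])]
      lab[only_alt] <- ifelse(touches, "GainedEdge", "GainedLAD")
    }
    r <- rle(lab)
    ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1L
    for (j in seq_along(r$values)) {
      cat_ <- r$values[j]
      if (cat_ == "iLAD") next
      acc[[cat_]]$chrom <- c(acc[[cat_]]$chrom, ch)
      acc[[cat_]]$start <- c(acc[[cat_]]$start, pos[starts_i[j]])
      acc[[cat_]]$end <- c(acc[[cat_]]$end,
                           min(pos[ends_i[j]] + resolution, lens[[ch]]))
    }
  }
  sets <- lapply(change_categories(), function(cat_) {
    domain_set(ref$assembly, acc[[cat_]]$chrom, acc[[cat_]]$start,
               acc[[cat_]]$end, label = cat_)
  })
  names(sets) <- change_categories()
  structure(c(sets, list(assembly = ref$assembly,
                         ref_label = ref$label, alt_label = alt$label)),
            class = "LADChangeMap")
}

# position membership / covering-domain index computed by scalar logic
positions_in <- function(pos, domains, ch) {
  df <- as.data.frame(domains)
  df <- df[df$chrom == ch, , drop = FALSE]
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(df))) out[pos >= df$start[i] & pos < df$end[i]] <- TRUE
  out
}

covering_domain_id <- function(pos, domains, ch) {
  df <- as.data.frame(domains)
  df <- df[df$chrom == ch, , drop = FALSE]
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(df))) out[pos >= df$start[i] & pos < df$end[i]] <- i
  out
}

#' Per-category coverage totals
#'
#' @param map an `LADChangeMap`.
#' @param mb_digits decimals for the Mb column (default 0, the usual
#'   whole-Mb reporting style).
#' @param denominator `"union"` (default; percentage base is
#'   `|ref U alt|`) or `"genome"`.
#' @return A `CategoryTotals`: data.frame with `category`, `bp`, `mb`,
#'   `percent`, plus attributes `net_change_mb` (gain minus loss),
#'   `denominator_bp` and `denominator`.
#' @export
category_totals <- function(map, mb_digits = 0,
                            denominator = c("union", "genome")) {
  denominator <- match.arg(denominator)
  bp <- vapply(change_categories(), function(cat_) coverage_bp(map[[cat_]]), 1.0)
  ref_bp <- bp[["cLAD"]] + bp[["LostLAD"]] + bp[["LostEdge"]]
  alt_bp <- bp[["cLAD"]] + bp[["GainedLAD"]] + bp[["GainedEdge"]]
  union_bp <- sum(bp)                     # categories partition ref U alt
  den <- if (denominator == "union") union_bp else genome_size(map$assembly)
  out <- data.frame(category = change_categories(), bp = unname(bp),
                    mb = bp_to_mb(unname(bp), mb_digits),
                    percent = if (den > 0) unname(bp) / den * 100 else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "net_change_mb") <-
    (bp[["GainedLAD"]] + bp[["GainedEdge"]] -
       bp[["LostLAD"]] - bp[["LostEdge"]]) / 1e6
  attr(out, "ref_bp") <- ref_bp
  attr(out, "alt_bp") <- alt_bp
  attr(out, "denominator_bp") <- den
  attr(out, "denominator") <- denominator
  class(out) <- c("CategoryTotals", "data.frame")
  out
}

#' @export
print.CategoryTotals <- function(x, ...) {
  cat(sprintf("Category totals (%% of %s, %.1f Mb); net change %+.1f Mb\n",
              attr(x, "denominator"), attr(x, "denominator_bp") / 1e6,
              attr(x, "net_change_mb")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Domain sizes within a change category
#'
#' @param map an `LADChangeMap`.
#' @param category one of [change_categories()].
#' @return List with `sizes` (bp of each maximal interval), `count`,
#'   `mean`, `median` (`NA` with a warning when the category is empty).
#' @export
domain_size_distribution <- function(map, category) {
  if (!category %in% change_categories()) stop("unknown category: ", category)
  sizes <- as.numeric(GenomicRanges::width(map[[category]]$gr))
  if (!length(sizes)) {
    warning("category '", category, "' is empty; mean/median undefined")
    return(list(sizes = numeric(), count = 0L, mean = NA_real_,
                median = NA_real_))
  }
  list(sizes = sizes, count = length(sizes), mean = mean(sizes),
       median = stats::median(sizes))
}

#' Base-level agreement between two change maps
#'
#' Fraction of the genome assigned the same (six-way, including implicit
#' inter-LAD) label by two change maps. Used to score recovery of a
#' planted truth map from noisy data.
#'
#' @param map,truth `LADChangeMap`s on one assembly.
#' @return Agreement fraction in [0, 1].
#' @export
change_map_accuracy <- function(map, truth) {
  stopifnot(inherits(map, "LADChangeMap"), inherits(truth, "LADChangeMap"))
  check_same_assembly(map$cLAD, truth$cLAD)
  total <- genome_size(map$assembly)
  agree <- 0
  for (cat_ in change_categories()) {
    agree <- agree + coverage_bp(ds_intersect(map[[cat_]], truth[[cat_]]))
  }
  all_map <- Reduce(ds_union, lapply(change_categories(), function(c_) map[[c_]]))
  all_truth <- Reduce(ds_union, lapply(change_categories(), function(c_) truth[[c_]]))
  # implicit i-LAD agreement: genome outside both maps' covered regions
  union_cov <- coverage_bp(ds_union(all_map, all_truth))
  agree <- agree + (total - union_cov)
  agree / total
}
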