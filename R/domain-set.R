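#' Construct a domain set
#'
#' A `DomainSet` is a sorted, pairwise-disjoint set of genomic intervals on
#' a fixed assembly — the representation of one condition's LADs (or KDDs,
#' KMDs, peak calls...). Coordinates at the user interface are 0-based
#' half-open (BED convention); internally intervals are held as a
#' [GenomicRanges::GRanges].
#'
#' @param assembly a `Seqinfo` assembly (see [genome_assembly()]).
#' @param chrom,start,end parallel vectors defining intervals; `start` is
#'   0-based inclusive, `end` exclusive. All may be empty.
#' @param label free-text label for the set (e.g. `"WT"`).
#' @param merge if `TRUE`, overlapping intervals are coalesced; if `FALSE`
#'   (default) overlap is an error (the invariant is disjointness).
#' @param merge_touching when merging, also coalesce book-ended intervals
#'   (end of one equals start of the next). Default `TRUE`.
#' @return A `DomainSet`.
#' @examples
#' asm <- genome_assembly("chrT", 1e6)
#' domain_set(asm, "chrT", c(0, 500e3), c(100e3, 600e3), label = "WT")
#' @export
domain_set <- function(assembly, chrom = character(), start = numeric(),
                       end = numeric(), label = "domains",
                       merge = FALSE, merge_touching = TRUE) {
  if (length(chrom) == 1L && length(start) > 1L) chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(chrom)) {
    known <- GenomeInfoDb::seqnames(assembly)
    bad <- setdiff(unique(chrom), known)
    if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
    if (any(start >= end)) stop("zero- or negative-length interval(s)")
    if (any(start < 0)) stop("negative start coordinate(s)")
    lens <- GenomeInfoDb::seqlengths(assembly)[chrom]
    if (any(end > lens)) stop("interval(s) extend beyond chromosome end")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = GenomeInfoDb::seqnames(assembly)),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    seqinfo = assembly)
  gr <- GenomicRanges::sort(gr)
  if (merge) {
    gr <- GenomicRanges::reduce(gr, min.gapwidth = if (merge_touching) 1L else 0L)
  } else {
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    if (length(red) != length(gr)) stop("overlapping intervals in DomainSet")
  }
  new_domain_set(gr, label)
}

# Internal: wrap an already-valid reduced GRanges.
new_domain_set <- function(gr, label = "domains") {
  structure(list(gr = gr,
                 assembly = GenomeInfoDb::seqinfo(gr),
                 label = label),
            class = "DomainSet")
}

# Internal: DomainSet from a GRanges, reducing to enforce invariants.
domain_set_from_granges <- function(gr, label = "domains", merge_touching = TRUE) {
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr),
                              min.gapwidth = if (merge_touching) 1L else 0L)
  GenomicRanges::strand(gr) <- "*"
  S4Vectors::mcols(gr) <- NULL
  new_domain_set(gr, label)
}

#' @export
print.DomainSet <- function(x, ...) {
  cat(sprintf("DomainSet '%s': %d interval(s), %.3f Mb on %d chromosome(s)\n",
              x$label, length(x$gr), bp_to_mb(coverage_bp(x), 3),
              length(GenomeInfoDb::seqnames(x$assembly))))
  invisible(x)
}

#' @export
as.data.frame.DomainSet <- function(x, ...) {
  gr <- x$gr
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' @export
length.DomainSet <- function(x) length(x$gr)

#' Total coverage of a domain set in bp
#'
#' @param domains a `DomainSet`.
#' @return Coverage in bp (numeric).
#' @export
coverage_bp <- function(domains) {
  sum(as.numeric(GenomicRanges::width(domains$gr)))
}

#' Convert bp to megabases
#'
#' @param bp base pairs.
#' @param digits decimals to round to (default 0, the style used for
#'   domain-coverage reporting).
#' @return bp / 1e6, rounded.
#' @export
bp_to_mb <- function(bp, digits = 0) round(bp / 1e6, digits)

#' Tile a domain set into fixed-width windows
#'
#' Splits every interval into consecutive windows of at most `width` bp
#' (the final window of an interval may be shorter). Useful for turning
#' broad domains into site-scale intervals for annotation.
#'
#' @param domains a `DomainSet`.
#' @param width window width in bp.
#' @return A `DomainSet` of the tiles (book-ended tiles are kept separate).
#' @export
tile_domains <- function(domains, width = 10000) {
  stopifnot(width >= 1)
  tiles <- unlist(GenomicRanges::slidingWindows(domains$gr, width = as.integer(width),
                                                step = as.integer(width)),
                  use.names = FALSE)
  new_domain_set(GenomicRanges::sort(tiles),
                 paste0(domains$label, ".tiles"))
}

# ---- internal set algebra on DomainSets (base-level semantics) -----------

ds_union <- function(a, b, label = "union") {
  check_same_assembly(a, b)
  domain_set_from_granges(c(a$gr, b$gr), label)
}

ds_intersect <- function(a, b, label = "intersect") {
  check_same_assembly(a, b)
  domain_set_from_granges(GenomicRanges::intersect(a$gr, b$gr), label)
}

ds_setdiff <- function(a, b, label = "setdiff") {
  check_same_assembly(a, b)
  domain_set_from_granges(GenomicRanges::setdiff(a$gr, b$gr), label)
}

# Equality at base resolution.
ds_equal <- function(a, b) {
  ga <- GenomicRanges::reduce(a$gr, min.gapwidth = 1L)
  gb <- GenomicRanges::reduce(b$gr, min.gapwidth = 1L)
  length(ga) == length(gb) &&
    all(as.character(GenomicRanges::seqnames(ga)) ==
          as.character(GenomicRanges::seqnames(gb))) &&
    all(GenomicRanges::start(ga) == GenomicRanges::start(gb)) &&
    all(GenomicRanges::end(ga) == GenomicRanges::end(gb))
}
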