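#' Construct a genome assembly
#'
#' An assembly is the coordinate frame shared by every object in the
#' package: an ordered set of chromosomes with their lengths. It is stored
#' as a [GenomeInfoDb::Seqinfo] so that interval operations respect
#' chromosome bounds.
#'
#' @param chroms character vector of chromosome names (unique).
#' @param lengths integer vector of chromosome lengths in bp (positive).
#' @return A `Seqinfo` object.
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(1e7, 5e6))
#' @export
genome_assembly <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  if (length(chroms) == 0L) stop("assembly needs at least one chromosome")
  if (anyDuplicated(chroms)) {
    stop("duplicate chromosome name(s): ",
         paste(unique(chroms[duplicated(chroms)]), collapse = ", "))
  }
  if (length(lengths) != length(chroms)) {
    stop("chroms and lengths differ in length")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != round(lengths))) {
    stop("chromosome lengths must be positive integers")
  }
  GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = as.integer(lengths))
}

#' Read a chrom.sizes file
#'
#' Parses the two-column whitespace-separated format (name, length) used by
#' UCSC `chrom.sizes` files. Chromosome order in the file is preserved.
#'
#' @param path path to a chrom.sizes file.
#' @return A `Seqinfo` assembly.
#' @export
load_assembly <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, col.names = c("chrom", "length"),
                      colClasses = c("character", "numeric")),
    error = function(e) stop("cannot parse chrom.sizes file '", path, "': ",
                             conditionMessage(e)))
  if (nrow(tab) == 0L) stop("empty chrom.sizes file: ", path)
  genome_assembly(tab$chrom, tab$length)
}

#' Total genome size of an assembly
#'
#' @param assembly a `Seqinfo` assembly.
#' @return Total length in bp.
#' @export
genome_size <- function(assembly) {
  sum(as.numeric(GenomeInfoDb::seqlengths(assembly)))
}

# Check two objects share an identical assembly.
check_same_assembly <- function(...) {
  sis <- lapply(list(...), assembly_of)
  ref <- sis[[1L]]
  for (si in sis[-1L]) {
    if (!identical(GenomeInfoDb::seqnames(ref), GenomeInfoDb::seqnames(si)) ||
        !identical(GenomeInfoDb::seqlengths(ref), GenomeInfoDb::seqlengths(si))) {
      stop("assembly mismatch between inputs")
    }
  }
  invisible(ref)
}

# Extract the Seqinfo from package objects.
assembly_of <- function(x) {
  if (methods::is(x, "Seqinfo")) return(x)
  if (inherits(x, c("DomainSet", "BinnedTrack", "GeneSet", "LADChangeMap"))) {
    return(x$assembly)
  }
  if (methods::is(x, "GRanges")) return(GenomeInfoDb::seqinfo(x))
  stop("cannot extract an assembly from an object of class ",
       paste(class(x), collapse = "/"))
}
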