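#' Read domain calls from a BED file
#'
#' Accepts BED3 or richer; only the first three columns are used. Records
#' must fall within the assembly. Overlapping records are merged into
#' maximal intervals; book-ended records are merged only when
#' `merge_touching = TRUE`.
#'
#' @param path BED file path.
#' @param assembly a `Seqinfo` assembly.
#' @param merge_touching merge book-ended records (default `TRUE`).
#' @param label label for the resulting set (default: file base name).
#' @return A `DomainSet`.
#' @export
load_domains <- function(path, assembly, merge_touching = TRUE,
                         label = NULL) {
  if (is.null(label)) label <- sub("\\.bed$", "", basename(path))
  if (file.size(path) == 0L) {
    return(domain_set(assembly, label = label))
  }
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  domain_set(assembly, df$chrom, df$start, df$end, label = label,
             merge = TRUE, merge_touching = merge_touching)
}

#' Write a domain set as BED3
#'
#' Intervals are written in genome order with 0-based half-open
#' coordinates, so `load_domains(save_domains(d))` round-trips exactly.
#'
#' @param domains a `DomainSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_domains <- function(domains, path) {
  df <- as.data.frame(domains)
  # write.table on a 0-row frame still produces an empty file
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a binned signal track
#'
#' Fixed-width per-chromosome bins holding (log2) enrichment values. The
#' last bin of each chromosome may cover fewer bp than `bin_size`. `NA`
#' marks bins without signal; missing bins are excluded from all means,
#' never treated as zero.
#'
#' @param assembly a `Seqinfo` assembly.
#' @param bin_size bin width in bp (> 0).
#' @param values named list (one numeric vector per chromosome) or `NULL`
#'   to create an all-missing track.
#' @return A `BinnedTrack`.
#' @export
binned_track <- function(assembly, bin_size, values = NULL) {
  stopifnot(bin_size >= 1)
  bin_size <- as.integer(bin_size)
  lens <- GenomeInfoDb::seqlengths(assembly)
  nbins <- ceiling(lens / bin_size)
  if (is.null(values)) {
    values <- lapply(nbins, function(n) rep(NA_real_, n))
  }
  if (!identical(sort(names(values)), sort(names(lens)))) {
    stop("track values must cover exactly the assembly's chromosomes")
  }
  values <- values[names(lens)]
  for (ch in names(lens)) {
    if (length(values[[ch]]) != nbins[[ch]]) {
      stop(sprintf("chromosome %s: expected %d bins, got %d",
                   ch, nbins[[ch]], length(values[[ch]])))
    }
  }
  structure(list(assembly = assembly, bin_size = bin_size,
                 values = values),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  n <- sum(vapply(x$values, length, 1L))
  miss <- sum(vapply(x$values, function(v) sum(is.na(v)), 1L))
  cat(sprintf("BinnedTrack: %d bins of %d bp (%d missing)\n",
              n, x$bin_size, miss))
  invisible(x)
}

#' Read a bedGraph file into fixed-width bins
#'
#' Each bin's value is the coverage-weighted mean of the bedGraph records
#' overlapping it; bins with no record are missing (`NA`). Overlapping
#' bedGraph records are rejected as ambiguous.
#'
#' @param path bedGraph file path.
#' @param assembly a `Seqinfo` assembly.
#' @param bin_size bin width in bp.
#' @return A `BinnedTrack`.
#' @export
load_track <- function(path, assembly, bin_size = 10000) {
  raw <- rtracklayer::import(path, format = "bedGraph")
  known <- GenomeInfoDb::seqnames(assembly)
  chroms <- as.character(GenomicRanges::seqnames(raw))
  bad <- setdiff(unique(chroms), known)
  if (length(bad)) stop("unknown chromosome(s) in bedGraph: ",
                        paste(bad, collapse = ", "))
  lens <- GenomeInfoDb::seqlengths(assembly)[chroms]
  if (length(raw) && any(GenomicRanges::end(raw) > lens)) {
    stop("bedGraph record(s) extend beyond chromosome end")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chroms, levels = known),
    ranges = GenomicRanges::ranges(raw),
    seqinfo = assembly, score = S4Vectors::mcols(raw)$score)
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1L)) {
    stop("overlapping bedGraph records are ambiguous")
  }
  track_from_granges(gr, assembly, bin_size)
}

# Shared binning kernel: GRanges with a 'score' mcol -> BinnedTrack.
track_from_granges <- function(gr, assembly, bin_size) {
  bin_size <- as.integer(bin_size)
  lens <- GenomeInfoDb::seqlengths(assembly)
  values <- lapply(names(lens), function(ch) {
    n <- ceiling(lens[[ch]] / bin_size)
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    out <- rep(NA_real_, n)
    if (!length(sub)) return(out)
    s0 <- GenomicRanges::start(sub) - 1L   # 0-based
    e0 <- GenomicRanges::end(sub)
    v <- S4Vectors::mcols(sub)$score
    wsum <- numeric(n); vsum <- numeric(n)
    for (i in seq_along(sub)) {
      b0 <- s0[i] %/% bin_size
      b1 <- (e0[i] - 1L) %/% bin_size
      for (b in b0:b1) {
        lo <- max(s0[i], b * bin_size)
        hi <- min(e0[i], (b + 1) * bin_size)
        w <- hi - lo
        wsum[b + 1L] <- wsum[b + 1L] + w
        vsum[b + 1L] <- vsum[b + 1L] + w * v[i]
      }
    }
    covered <- wsum > 0
    out[covered] <- vsum[covered] / wsum[covered]
    out
  })
  names(values) <- names(lens)
  binned_track(assembly, bin_size, values)
}

#' Write a binned track as bedGraph
#'
#' Missing bins are omitted from the output.
#'
#' @param track a `BinnedTrack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_track <- function(track, path) {
  lens <- GenomeInfoDb::seqlengths(track$assembly)
  bs <- track$bin_size
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(lens)) {
    v <- track$values[[ch]]
    keep <- which(!is.na(v))
    if (!length(keep)) next
    starts <- (keep - 1L) * bs
    ends <- pmin(keep * bs, lens[[ch]])
    utils::write.table(
      data.frame(ch, starts, ends, v[keep]),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# ---- gene models ---------------------------------------------------------

#' Construct a gene set
#'
#' @param assembly a `Seqinfo` assembly.
#' @param genes a data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `start`, `end` (transcript span, 0-based half-open), and
#'   optionally `cds_start`, `cds_end` (`NA` when absent).
#' @param exons a named list (by `gene_id`) of two-column matrices or
#'   data.frames of exon `start`/`end` (0-based half-open), sorted and
#'   disjoint, nested in the transcript span.
#' @return A `GeneSet`.
#' @export
gene_set <- function(assembly, genes, exons) {
  req <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(req %in% names(genes))) {
    stop("genes table needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene id(s)")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  known <- GenomeInfoDb::seqnames(assembly)
  if (!all(genes$chrom %in% known)) stop("unknown chromosome in gene table")
  if (any(genes$start >= genes$end)) stop("empty transcript span")
  lens <- GenomeInfoDb::seqlengths(assembly)[genes$chrom]
  if (any(genes$start < 0) || any(genes$end > lens)) {
    stop("transcript outside chromosome bounds")
  }
  if (is.null(genes$cds_start)) genes$cds_start <- rep(NA_real_, nrow(genes))
  if (is.null(genes$cds_end)) genes$cds_end <- rep(NA_real_, nrow(genes))
  has_cds <- !is.na(genes$cds_start)
  if (any(has_cds & (genes$cds_start < genes$start |
                     genes$cds_end > genes$end |
                     genes$cds_start >= genes$cds_end), na.rm = TRUE)) {
    stop("CDS not nested in transcript span")
  }
  exons <- exons[genes$gene_id]
  for (i in seq_len(nrow(genes))) {
    ex <- as.data.frame(exons[[genes$gene_id[i]]])
    if (is.null(ex) || nrow(ex) == 0L) stop("gene without exons: ", genes$gene_id[i])
    names(ex)[1:2] <- c("start", "end")
    if (is.unsorted(ex$start, strictly = TRUE) ||
        any(ex$start >= ex$end) ||
        any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("exons must be sorted and disjoint: ", genes$gene_id[i])
    }
    if (ex$start[1] < genes$start[i] || ex$end[nrow(ex)] > genes$end[i]) {
      stop("exon outside transcript span: ", genes$gene_id[i])
    }
    exons[[genes$gene_id[i]]] <- ex
  }
  rownames(genes) <- NULL
  structure(list(assembly = assembly, genes = genes, exons = exons),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet: %d gene(s) on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

#' @export
length.GeneSet <- function(x) nrow(x$genes)

#' Transcription start sites of a gene set
#'
#' TSS is the transcript start for `+` strand genes and `end - 1` (the
#' last transcribed base, 0-based) for `-` strand genes.
#'
#' @param genes a `GeneSet`.
#' @return data.frame with `gene_id`, `chrom`, `strand`, `tss` (0-based).
#' @export
gene_tss <- function(genes) {
  g <- genes$genes
  data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             tss = ifelse(g$strand == "+", g$start, g$end - 1),
             stringsAsFactors = FALSE)
}

#' Read gene models from GTF or a simplified gene TSV
#'
#' GTF input (1-based closed, converted on parse) must carry `gene`,
#' `exon` and optionally `CDS` features with `gene_id` attributes. The TSV
#' alternative has header columns `gene_id`, `chrom`, `strand`, `start`,
#' `end`, `cds_start`, `cds_end`, `exon_starts`, `exon_ends` with 0-based
#' half-open coordinates and comma-separated exon lists; empty
#' `cds_start`/`cds_end` mean no annotated CDS.
#'
#' @param path GTF (`.gtf`) or TSV file.
#' @param assembly a `Seqinfo` assembly.
#' @return A `GeneSet`.
#' @export
load_genes <- function(path, assembly) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    load_genes_gtf(path, assembly)
  } else {
    load_genes_tsv(path, assembly)
  }
}

load_genes_gtf <- function(path, assembly) {
  gr <- rtracklayer::import(path, format = "gtf")
  typ <- as.character(S4Vectors::mcols(gr)$type)
  gid <- as.character(S4Vectors::mcols(gr)$gene_id)
  if (any(is.na(gid))) stop("GTF record without gene_id")
  gene_rows <- which(typ == "gene")
  if (!length(gene_rows)) stop("GTF has no 'gene' features")
  g <- gr[gene_rows]
  genes <- data.frame(
    gene_id = gid[gene_rows],
    chrom = as.character(GenomicRanges::seqnames(g)),
    strand = as.character(GenomicRanges::strand(g)),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::end(g),
    cds_start = NA_real_, cds_end = NA_real_,
    stringsAsFactors = FALSE)
  if (any(!genes$strand %in% c("+", "-"))) stop("gene without strand in GTF")
  cds_rows <- which(typ == "CDS")
  if (length(cds_rows)) {
    cs <- tapply(GenomicRanges::start(gr[cds_rows]) - 1L, gid[cds_rows], min)
    ce <- tapply(GenomicRanges::end(gr[cds_rows]), gid[cds_rows], max)
    idx <- match(names(cs), genes$gene_id)
    genes$cds_start[idx] <- as.numeric(cs)
    genes$cds_end[idx] <- as.numeric(ce)
  }
  exon_rows <- which(typ == "exon")
  exons <- lapply(genes$gene_id, function(id) {
    er <- gr[exon_rows][gid[exon_rows] == id]
    er <- GenomicRanges::sort(er)
    data.frame(start = GenomicRanges::start(er) - 1L,
               end = GenomicRanges::end(er))
  })
  names(exons) <- genes$gene_id
  gene_set(assembly, genes, exons)
}

load_genes_tsv <- function(path, assembly) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("gene_id", "chrom", "strand", "start", "end",
           "exon_starts", "exon_ends")
  if (!all(req %in% names(tab))) {
    stop("gene TSV needs columns: ", paste(req, collapse = ", "))
  }
  exons <- lapply(seq_len(nrow(tab)), function(i) {
    data.frame(
      start = as.numeric(strsplit(as.character(tab$exon_starts[i]), ",")[[1]]),
      end = as.numeric(strsplit(as.character(tab$exon_ends[i]), ",")[[1]]))
  })
  names(exons) <- tab$gene_id
  gene_set(assembly, tab[setdiff(names(tab), c("exon_starts", "exon_ends"))],
           exons)
}

#' Write a gene set as the simplified gene TSV
#'
#' @param genes a `GeneSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_genes <- function(genes, path) {
  g <- genes$genes
  g$exon_starts <- vapply(genes$exons[g$gene_id],
                          function(e) paste(e$start, collapse = ","), "")
  g$exon_ends <- vapply(genes$exons[g$gene_id],
                        function(e) paste(e$end, collapse = ","), "")
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- expression tables ---------------------------------------------------

#' Read a differential-expression table
#'
#' Expects a TSV holding one row per gene with a gene id, a log2 fold
#' change and an FDR (q-value). Column names are configurable to match
#' whatever the upstream DE tool emitted.
#'
#' @param path TSV path.
#' @param id_col,lfc_col,fdr_col,basemean_col header names (defaults
#'   `gene_id`, `log2fc`, `fdr`, `base_mean`; the base-mean column is
#'   optional).
#' @return An `ExpressionTable`: data.frame with columns `gene_id`,
#'   `log2fc`, `fdr` and optionally `base_mean`.
#' @export
load_expression <- function(path, id_col = "gene_id", lfc_col = "log2fc",
                            fdr_col = "fdr", basemean_col = "base_mean") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (col in c(id_col, lfc_col, fdr_col)) {
    if (!col %in% names(tab)) stop("missing column: ", col)
  }
  out <- data.frame(gene_id = as.character(tab[[id_col]]),
                    log2fc = tab[[lfc_col]], fdr = tab[[fdr_col]],
                    stringsAsFactors = FALSE)
  if (basemean_col %in% names(tab)) out$base_mean <- tab[[basemean_col]]
  expression_table(out)
}

#' Validate an expression table
#'
#' @param tab data.frame with `gene_id`, `log2fc`, `fdr` (and optionally
#'   `base_mean`).
#' @return The validated table, classed `ExpressionTable`.
#' @export
expression_table <- function(tab) {
  if (nrow(tab) == 0L) {
    warning("empty expression table")
  } else {
    if (anyDuplicated(tab$gene_id)) stop("duplicate gene id(s) in expression table")
    if (!is.numeric(tab$log2fc) || !is.numeric(tab$fdr)) {
      stop("log2fc and fdr must be numeric")
    }
    if (any(is.na(tab$fdr)) || any(tab$fdr < 0 | tab$fdr > 1)) {
      stop("fdr values must lie in [0, 1]")
    }
  }
  class(tab) <- c("ExpressionTable", "data.frame")
  tab
}
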