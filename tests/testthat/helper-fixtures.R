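# Shared fixtures and independent oracles for the test suite.

toy_assembly <- function(lengths = c(chrT = 1e6)) {
  genome_assembly(names(lengths), lengths)
}

# Quick DomainSet from interleaved start/end pairs on one chromosome.
ds1 <- function(assembly, starts, ends, chrom = "chrT", label = "d") {
  domain_set(assembly, rep(chrom, length(starts)), starts, ends, label = label)
}

# Random disjoint domain set: up to n_max intervals with >= 2 bp gaps.
random_domain_set <- function(assembly, n_max = 20, label = "rand") {
  lens <- GenomeInfoDb::seqlengths(assembly)
  chrom <- character(); start <- numeric(); end <- numeric()
  for (ch in names(lens)) {
    n <- sample.int(n_max, 1)
    # 2n sorted distinct breakpoints -> n disjoint intervals
    pts <- sort(sample.int(lens[[ch]] - 1, 2 * n))
    s <- pts[seq(1, 2 * n, by = 2)]
    e <- pts[seq(2, 2 * n, by = 2)]
    keep <- e > s
    # drop book-ended neighbours so sets stay unambiguous
    if (sum(keep) > 1) {
      ss <- s[keep]; ee <- e[keep]
      keep2 <- c(TRUE, ss[-1] > ee[-length(ee)])
      ss <- ss[keep2]; ee <- ee[keep2]
    } else {
      ss <- s[keep]; ee <- e[keep]
    }
    chrom <- c(chrom, rep(ch, length(ss)))
    start <- c(start, ss); end <- c(end, ee)
  }
  domain_set(assembly, chrom, start, end, label = label)
}

# Per-base membership oracle for Venn coverage on small genomes.
venn_bruteforce <- function(a, b, c) {
  lens <- GenomeInfoDb::seqlengths(a$assembly)
  mask <- function(ds, ch) {
    v <- rep(FALSE, lens[[ch]])
    df <- as.data.frame(ds)
    df <- df[df$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(df))) v[(df$start[i] + 1):df$end[i]] <- TRUE
    v
  }
  tot <- c(A.only = 0, B.only = 0, C.only = 0, AB = 0, AC = 0, BC = 0, ABC = 0)
  for (ch in names(lens)) {
    ma <- mask(a, ch); mb <- mask(b, ch); mc <- mask(c, ch)
    tot["A.only"] <- tot["A.only"] + sum(ma & !mb & !mc)
    tot["B.only"] <- tot["B.only"] + sum(!ma & mb & !mc)
    tot["C.only"] <- tot["C.only"] + sum(!ma & !mb & mc)
    tot["AB"] <- tot["AB"] + sum(ma & mb & !mc)
    tot["AC"] <- tot["AC"] + sum(ma & !mb & mc)
    tot["BC"] <- tot["BC"] + sum(!ma & mb & mc)
    tot["ABC"] <- tot["ABC"] + sum(ma & mb & mc)
  }
  tot
}

# Full-enumeration Fisher oracle: probabilities from log-binomials,
# two-sided by summing table probabilities <= the observed one.
fisher_oracle <- function(a, b, cc, d) {
  rs1 <- a + b; rs2 <- cc + d; cs1 <- a + cc
  n <- rs1 + rs2
  if (rs1 == 0 || rs2 == 0 || cs1 == 0 || (n - cs1) == 0) return(1)
  support <- max(0, cs1 - rs2):min(rs1, cs1)
  logp <- lchoose(rs1, support) + lchoose(rs2, cs1 - support) - lchoose(n, cs1)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Hand-built three-gene toy genome used by the annotation tests:
#   geneA chrT + [50000, 70000) exons [50000,52000)+[60000,70000),
#         CDS 51000-65000 (5'UTR [50000,51000), 3'UTR [65000,70000))
#   geneC chrT + [300000, 320000) single-exon-like pair, no CDS
#   geneB chr2 - [200000, 240000) (TSS at 239999)
toy_genes <- function() {
  asm <- genome_assembly(c("chrT", "chr2"), c(2e6, 1e6))
  genes <- data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("chrT", "chr2", "chrT"),
    strand = c("+", "-", "+"),
    start = c(50000, 200000, 300000),
    end = c(70000, 240000, 320000),
    cds_start = c(51000, 205000, NA),
    cds_end = c(65000, 235000, NA),
    stringsAsFactors = FALSE)
  exons <- list(
    geneA = data.frame(start = c(50000, 60000), end = c(52000, 70000)),
    geneB = data.frame(start = c(200000, 220000), end = c(210000, 240000)),
    geneC = data.frame(start = c(300000, 315000), end = c(310000, 320000)))
  gene_set(asm, genes, exons)
}

# Coordinate mirror: position p -> L - p (strands flip, exon order reverses).
mirror_domains <- function(ds) {
  lens <- GenomeInfoDb::seqlengths(ds$assembly)
  df <- as.data.frame(ds)
  domain_set(ds$assembly, df$chrom, lens[df$chrom] - df$end,
             lens[df$chrom] - df$start, label = ds$label)
}

mirror_genes <- function(gs) {
  lens <- GenomeInfoDb::seqlengths(gs$assembly)
  g <- gs$genes
  L <- lens[g$chrom]
  new_g <- data.frame(
    gene_id = g$gene_id, chrom = g$chrom,
    strand = ifelse(g$strand == "+", "-", "+"),
    start = L - g$end, end = L - g$start,
    cds_start = ifelse(is.na(g$cds_start), NA, L - g$cds_end),
    cds_end = ifelse(is.na(g$cds_end), NA, L - g$cds_start),
    stringsAsFactors = FALSE)
  new_ex <- lapply(seq_len(nrow(g)), function(i) {
    ex <- gs$exons[[g$gene_id[i]]]
    Lc <- lens[[g$chrom[i]]]
    data.frame(start = rev(Lc - ex$end), end = rev(Lc - ex$start))
  })
  names(new_ex) <- g$gene_id
  gene_set(gs$assembly, new_g, new_ex)
}

# Step track: mu_in over the domain set, mu_out elsewhere, given bin size.
step_track <- function(assembly, domains, mu_in, mu_out, bin_size) {
  lens <- GenomeInfoDb::seqlengths(assembly)
  df <- as.data.frame(domains)
  vals <- lapply(names(lens), function(ch) {
    n <- ceiling(lens[[ch]] / bin_size)
    mid <- (seq_len(n) - 1) * bin_size +
      pmin(bin_size, lens[[ch]] - (seq_len(n) - 1) * bin_size) / 2
    d <- df[df$chrom == ch, , drop = FALSE]
    inside <- rep(FALSE, n)
    for (i in seq_len(nrow(d))) inside[mid >= d$start[i] & mid < d$end[i]] <- TRUE
    ifelse(inside, mu_in, mu_out)
  })
  names(vals) <- names(lens)
  binned_track(assembly, bin_size, vals)
}

# Equality helper comparing all five categories of two change maps.
expect_same_map <- function(map, truth) {
  for (cat_ in change_categories()) {
    expect_true(ladscape:::ds_equal(map[[cat_]], truth[[cat_]]),
                label = paste("category", cat_, "identical"))
  }
}
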