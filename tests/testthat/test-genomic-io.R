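# IO layer: chrom.sizes, BED, bedGraph, gene models, expression tables.

test_that("load_assembly parses chrom.sizes and rejects invalid files", {
  f <- withr::local_tempfile(lines = "chrT\t1000000")
  asm <- load_assembly(f)
  expect_equal(GenomeInfoDb::seqnames(asm), "chrT")
  expect_equal(unname(GenomeInfoDb::seqlengths(asm)), 1000000L)

  dup <- withr::local_tempfile(lines = c("chr1\t100", "chr1\t200"))
  expect_error(load_assembly(dup), "duplicate")
  neg <- withr::local_tempfile(lines = "chr1\t-5")
  expect_error(load_assembly(neg), "positive")
  empty <- withr::local_tempfile(lines = character())
  expect_error(load_assembly(empty))
})

test_that("domain_set enforces the coordinate invariants", {
  asm <- toy_assembly()
  expect_error(domain_set(asm, "chrT", 100, 100), "length")
  expect_error(domain_set(asm, "chrT", 200, 100), "length")
  expect_error(domain_set(asm, "chrX", 0, 10), "unknown chromosome")
  expect_error(domain_set(asm, "chrT", 999999, 1000001), "beyond")
  expect_error(domain_set(asm, "chrT", c(0, 50), c(100, 150)), "overlapping")
  # book-ended intervals are legal when not merging
  d <- domain_set(asm, "chrT", c(0, 100), c(100, 200))
  expect_equal(length(d), 2L)
})

test_that("load_domains merges overlapping records and validates bounds", {
  asm <- toy_assembly()
  f <- withr::local_tempfile(lines = c("chrT\t0\t100", "chrT\t50\t150"))
  d <- load_domains(f, asm)
  expect_equal(as.data.frame(d), data.frame(chrom = "chrT", start = 0, end = 150))

  empty <- withr::local_tempfile(lines = character())
  expect_equal(length(load_domains(empty, asm)), 0L)

  zero <- withr::local_tempfile(lines = "chrT\t100\t100")
  expect_error(load_domains(zero, asm))

  over <- withr::local_tempfile(lines = "chrT\t999000\t1000500")
  expect_error(load_domains(over, asm), "beyond")
})

test_that("save/load round-trips arbitrary domain sets exactly", {
  asm <- genome_assembly(c("chr1", "chr2"), c(5e5, 3e5))
  set.seed(41)
  for (i in 1:20) {
    d <- random_domain_set(asm, n_max = 10)
    f <- withr::local_tempfile(fileext = ".bed")
    save_domains(d, f)
    d2 <- load_domains(f, asm)
    expect_true(ladscape:::ds_equal(d, d2))
  }
  # empty set -> empty file -> empty set
  f <- withr::local_tempfile(fileext = ".bed")
  save_domains(domain_set(asm), f)
  expect_equal(file.size(f), 0)
  expect_equal(length(load_domains(f, asm)), 0L)
})

test_that("load_track bins bedGraph records by coverage-weighted mean", {
  asm <- toy_assembly()
  f <- withr::local_tempfile(lines = "chrT\t0\t1000000\t2.0")
  tr <- load_track(f, asm, bin_size = 10000)
  expect_equal(tr$values$chrT, rep(2, 100))

  # two half-bin records: bin 0 mean = (0*5000 + 4*5000) / 10000 = 2
  f2 <- withr::local_tempfile(lines = c("chrT\t0\t5000\t0", "chrT\t5000\t10000\t4"))
  tr2 <- load_track(f2, asm, bin_size = 10000)
  expect_equal(tr2$values$chrT[1], 2)
  expect_true(all(is.na(tr2$values$chrT[-1])))

  ov <- withr::local_tempfile(lines = c("chrT\t0\t100\t1", "chrT\t50\t150\t2"))
  expect_error(load_track(ov, asm), "ambiguous")
  bad <- withr::local_tempfile(lines = "chrQ\t0\t100\t1")
  expect_error(load_track(bad, asm), "unknown chromosome")
})

test_that("load_track conserves mass on covered chromosomes", {
  asm <- genome_assembly("chrT", 100000)
  set.seed(7)
  # random disjoint cover of the whole chromosome
  cuts <- sort(sample(1:99999, 30))
  s <- c(0, cuts); e <- c(cuts, 100000)
  v <- round(stats::runif(length(s), -2, 2), 3)
  f <- withr::local_tempfile(
    lines = sprintf("chrT\t%d\t%d\t%g", s, e, v))
  for (bs in c(1000, 3000, 7000)) {
    tr <- load_track(f, asm, bin_size = bs)
    widths <- pmin(seq_len(length(tr$values$chrT)) * bs, 100000) -
      (seq_len(length(tr$values$chrT)) - 1) * bs
    expect_equal(sum(tr$values$chrT * widths), sum(v * (e - s)),
                 tolerance = 1e-9)
  }
})

test_that("track round-trip through bedGraph preserves values", {
  asm <- genome_assembly("chrT", 55000)   # last bin is partial
  vals <- list(chrT = c(1, NA, -0.5, 2, 0.25, 3))
  tr <- binned_track(asm, 10000, vals)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  save_track(tr, f)
  tr2 <- load_track(f, asm, bin_size = 10000)
  expect_equal(tr2$values$chrT, vals$chrT)
})

test_that("load_genes parses GTF with gene/exon/CDS features", {
  asm <- toy_assembly(c(chrT = 1e6))
  gtf <- withr::local_tempfile(fileext = ".gtf", lines = c(
    'chrT\tsrc\tgene\t10001\t20000\t.\t+\t.\tgene_id "g1";',
    'chrT\tsrc\texon\t10001\t12000\t.\t+\t.\tgene_id "g1";',
    'chrT\tsrc\texon\t15001\t20000\t.\t+\t.\tgene_id "g1";',
    'chrT\tsrc\tCDS\t11001\t18000\t.\t+\t.\tgene_id "g1";'))
  gs <- load_genes(gtf, asm)
  expect_equal(length(gs), 1L)
  g <- gs$genes[1, ]
  expect_equal(c(g$start, g$end), c(10000, 20000))     # 0-based half-open
  expect_equal(c(g$cds_start, g$cds_end), c(11000, 18000))
  expect_equal(gs$exons$g1$start, c(10000, 15000))
  expect_equal(gs$exons$g1$end, c(12000, 20000))

  bad <- withr::local_tempfile(fileext = ".gtf", lines = c(
    'chrT\tsrc\tgene\t10001\t20000\t.\t+\t.\tgene_id "g1";',
    'chrT\tsrc\texon\t25001\t26000\t.\t+\t.\tgene_id "g1";'))
  expect_error(load_genes(bad, asm), "exon outside transcript")
})

test_that("gene TSV round-trips and duplicate ids are rejected", {
  gs <- toy_genes()
  f <- withr::local_tempfile(fileext = ".tsv")
  save_genes(gs, f)
  gs2 <- load_genes(f, gs$assembly)
  expect_equal(gs2$genes, gs$genes)
  expect_equal(gs2$exons, gs$exons)

  dup <- gs$genes[c(1, 1), ]
  expect_error(gene_set(gs$assembly, dup, gs$exons), "duplicate")
  nostrand <- gs$genes; nostrand$strand[1] <- "."
  expect_error(gene_set(gs$assembly, nostrand, gs$exons), "strand")
})

test_that("load_expression validates the DE table", {
  f <- withr::local_tempfile(lines = c("gene_id\tlog2fc\tfdr",
                                       "geneA\t-0.58\t0.01"))
  tab <- load_expression(f)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$log2fc, -0.58)

  bad <- withr::local_tempfile(lines = c("gene_id\tlog2fc\tfdr",
                                         "geneA\t0.5\t1.3"))
  expect_error(load_expression(bad), "\\[0, 1\\]")
  empty <- withr::local_tempfile(lines = "gene_id\tlog2fc\tfdr")
  expect_warning(tab0 <- load_expression(empty), "empty")
  expect_equal(nrow(tab0), 0L)
})
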