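# DE classification, Fisher enrichment, rank-sum comparison, ordination.

make_de <- function(n_down_gained, n_down_not, n_ns_gained, n_ns_not) {
  n <- n_down_gained + n_down_not + n_ns_gained + n_ns_not
  ids <- sprintf("g%03d", seq_len(n))
  down <- rep(c(TRUE, FALSE), c(n_down_gained + n_down_not,
                                n_ns_gained + n_ns_not))
  gained <- c(rep(TRUE, n_down_gained), rep(FALSE, n_down_not),
              rep(TRUE, n_ns_gained), rep(FALSE, n_ns_not))
  de <- data.frame(gene_id = ids, log2fc = ifelse(down, -1, 0),
                   fdr = ifelse(down, 0.01, 0.5),
                   status = factor(ifelse(down, "down", "ns"),
                                   levels = c("up", "down", "ns")),
                   stringsAsFactors = FALSE)
  st <- data.frame(gene_id = ids, gained = gained, lost = FALSE,
                   lad_status = factor(ifelse(gained, "gained", "none"),
                                       levels = c("gained", "lost", "both", "none")),
                   stringsAsFactors = FALSE)
  list(de = de, st = st)
}

test_that("classify_de applies the FDR and fold-change rule", {
  tab <- expression_table(data.frame(
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(-0.58, 1.5, 0.20, 0.30),
    fdr = c(0.01, 0.2, 0.01, 0.01)))
  de <- classify_de(tab)
  expect_equal(as.character(de$status), c("down", "ns", "ns", "up"))
  # -0.58 passes: 2^0.58 ~ 1.49 >= 1.2; 0.20 fails: 2^0.20 ~ 1.15 < 1.2
  expect_equal(as.character(de$status[de$gene_id == "a"]), "down")
  expect_equal(as.character(de$status[de$gene_id == "c"]), "ns")
  # invariant to row order
  de2 <- classify_de(tab[4:1, ])
  expect_equal(as.character(de2$status[match(de$gene_id, de2$gene_id)]),
               as.character(de$status))
})

test_that("assign_gene_domain_status uses gene-body overlap", {
  asm <- toy_assembly()
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chrT",
                      strand = "+", start = c(0, 5000, 20000),
                      end = c(1000, 6000, 30000), stringsAsFactors = FALSE)
  exons <- lapply(seq_len(3), function(i) {
    data.frame(start = genes$start[i], end = genes$end[i])
  })
  names(exons) <- genes$gene_id
  gs <- gene_set(asm, genes, exons)
  map <- classify_changes(ds1(asm, c(500, 25000), c(600, 26000)),
                          ds1(asm, 500, 600))
  # g1 overlaps cLAD only -> LostEdge? no: [500,600) kept, [25000,26000) lost
  st <- assign_gene_domain_status(gs, map)
  expect_equal(as.character(st$lad_status), c("none", "none", "lost"))
  map2 <- classify_changes(domain_set(asm), ds1(asm, 500, 600))
  st2 <- assign_gene_domain_status(gs, map2)
  expect_equal(as.character(st2$lad_status), c("gained", "none", "none"))
  # a gene overlapping both a gained and a lost category is 'both'
  map3 <- classify_changes(ds1(asm, 25000, 26000), ds1(asm, 500, 600))
  st3 <- assign_gene_domain_status(gs, map3)
  expect_equal(as.character(st3$lad_status[c(1, 3)]), c("gained", "lost"))
  big <- data.frame(gene_id = "g4", chrom = "chrT", strand = "+",
                    start = 0, end = 30000, stringsAsFactors = FALSE)
  gs4 <- gene_set(asm, big, list(g4 = data.frame(start = 0, end = 30000)))
  expect_equal(as.character(assign_gene_domain_status(gs4, map3)$lad_status),
               "both")
})

test_that("the Fisher construction matches its worked examples", {
  x <- make_de(5, 0, 0, 5)
  r <- gain_enrichment_test(x$de, x$st)
  expect_equal(r$p_value, 2 / 252)
  expect_true(is.infinite(r$odds_ratio))
  expect_true(r$corrected)
  expect_equal(r$odds_ratio_corrected, 121)
  expect_true(r$enriched)

  x2 <- make_de(5, 5, 5, 5)
  r2 <- gain_enrichment_test(x2$de, x2$st)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p_value, 1)
  expect_false(r2$enriched)

  # up-regulated genes are excluded from the contingency table
  x3 <- make_de(3, 3, 3, 3)
  x3$de$status[1] <- "up"
  r3 <- gain_enrichment_test(x3$de, x3$st)
  expect_equal(sum(r3$table), 11)

  # degenerate margin: no down-regulated gene -> p = 1 with a warning
  x4 <- make_de(0, 0, 4, 4)
  expect_warning(r4 <- gain_enrichment_test(x4$de, x4$st), "degenerate")
  expect_equal(r4$p_value, 1)
  expect_true(is.na(r4$odds_ratio))
})

test_that("Fisher p agrees with enumeration and stats::fisher.test", {
  set.seed(91)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 6), 2)
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
    p_impl <- ladscape:::fisher_2x2(a, b, cc, d)$p_value
    expect_equal(p_impl, fisher_oracle(a, b, cc, d), tolerance = 1e-12)
    if (sum(tab) > 0 && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expect_equal(p_impl, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("expression_by_lad compares groups with the rank-sum test", {
  asm <- toy_assembly()
  genes <- data.frame(gene_id = sprintf("g%d", 1:6), chrom = "chrT",
                      strand = "+", start = seq(0, 50000, by = 10000),
                      end = seq(0, 50000, by = 10000) + 1000,
                      stringsAsFactors = FALSE)
  exons <- lapply(1:6, function(i) data.frame(start = genes$start[i],
                                              end = genes$end[i]))
  names(exons) <- genes$gene_id
  gs <- gene_set(asm, genes, exons)
  lads <- ds1(asm, 0, 25000)            # first three genes inside
  tab <- expression_table(data.frame(
    gene_id = genes$gene_id, log2fc = 0, fdr = 0.5,
    base_mean = c(0, 0, 0, 5, 6, 7)))
  res <- expression_by_lad(gs, lads, tab)
  expect_equal(res$median_in, 0)
  expect_equal(res$median_out, 6)
  expect_equal(res$p_value, 0.1)        # smallest attainable for 3 vs 3
  expect_equal(res$method, "exact enumeration")

  # all-tied values: p = 1
  tab2 <- expression_table(data.frame(gene_id = genes$gene_id, log2fc = 0,
                                      fdr = 0.5, base_mean = 2))
  expect_equal(expression_by_lad(gs, lads, tab2)$p_value, 1)

  # a group empty -> error
  expect_error(expression_by_lad(gs, ds1(asm, 900000, 950000), tab),
               "empty")
})

test_that("rank-sum branches agree with stats::wilcox.test", {
  set.seed(17)
  # exact branch, no ties
  x <- stats::rnorm(5); y <- stats::rnorm(7) + 0.5
  got <- ladscape:::ranksum_test(x, y)
  expect_equal(got$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
  # approximate branch (large groups, tie-corrected, no continuity corr.)
  x2 <- round(stats::rnorm(40), 1); y2 <- round(stats::rnorm(60) + 0.3, 1)
  got2 <- ladscape:::ranksum_test(x2, y2)
  expect_equal(got2$method, "normal approximation")
  expect_equal(got2$p_value,
               suppressWarnings(stats::wilcox.test(
                 x2, y2, exact = FALSE, correct = FALSE)$p.value))
})

test_that("domain_overlap_pca has the expected geometry", {
  asm <- genome_assembly(c("chr1", "chr2"), c(1e6, 1e6))
  a <- domain_set(asm, "chr1", 0, 400000, label = "A")
  a2 <- domain_set(asm, "chr1", 0, 400000, label = "A2")
  b <- domain_set(asm, "chr2", c(100000, 600000), c(300000, 900000), label = "B")
  ord <- domain_overlap_pca(list(a, a2, b), bin_size = 50000)
  expect_equal(ord$distances["A", "A2"], 0)
  expect_gt(ord$distances["A", "B"], 0)
  expect_true(all(diff(ord$explained) <= 1e-12))
  expect_lte(sum(ord$explained), 1 + 1e-12)

  # cross-check coordinates against prcomp on the same coverage matrix
  pc <- stats::prcomp(ladscape:::domain_coverage_matrix(list(a, a2, b), 50000))
  d_pc <- as.matrix(stats::dist(pc$x))
  expect_equal(unname(ord$distances), unname(d_pc), tolerance = 1e-9)

  # all-identical sets: degenerate, zero coordinates, flagged
  expect_warning(z <- domain_overlap_pca(list(a, a2, a2)), "identical")
  expect_true(z$degenerate)
  expect_true(all(z$coords == 0))
  expect_error(domain_overlap_pca(list(a, b)), "at least 3")
})
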