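# The synthetic-data generator: planted architectures, tracks, genes,
# expression tables.

test_that("zero-edit scenarios leave KO identical to WT", {
  p <- scenario_params(n_gain = 0, n_loss = 0, n_extend = 0, n_retract = 0,
                       seed = 5)
  sc <- simulate_scenario(p)
  expect_true(ladscape:::ds_equal(sc$wt, sc$ko))
  expect_true(ladscape:::ds_equal(sc$truth$cLAD, sc$wt))
  for (cat_ in setdiff(change_categories(), "cLAD")) {
    expect_equal(length(sc$truth[[cat_]]), 0L)
  }
})

test_that("scenarios are deterministic given the seed", {
  a <- simulate_scenario(scenario_params(seed = 42))
  b <- simulate_scenario(scenario_params(seed = 42))
  expect_identical(as.data.frame(a$wt), as.data.frame(b$wt))
  expect_identical(as.data.frame(a$ko), as.data.frame(b$ko))
  cc <- simulate_scenario(scenario_params(seed = 43))
  expect_false(identical(as.data.frame(a$wt), as.data.frame(cc$wt)))
})

test_that("edit counts are realized exactly by construction", {
  p <- scenario_params(n_gain = 3, n_loss = 2, n_extend = 2, n_retract = 2,
                       seed = 9)
  sc <- simulate_scenario(p)
  expect_equal(length(sc$truth$GainedLAD), 3L)
  expect_equal(length(sc$truth$LostLAD), 2L)
  expect_equal(length(sc$truth$GainedEdge) + length(sc$truth$LostEdge), 4L)
})

test_that("truth edits applied to WT reproduce KO exactly", {
  for (s in 1:10) {
    sc <- simulate_scenario(scenario_params(seed = s))
    expect_true(ladscape:::ds_equal(apply_change_map(sc$wt, sc$truth), sc$ko))
  }
})

test_that("classify_changes recovers the planted truth map exactly", {
  for (s in 1:30) {
    sc <- simulate_scenario(scenario_params(seed = s))
    expect_same_map(classify_changes(sc$wt, sc$ko), sc$truth)
  }
})

test_that("an impossible architecture fails loudly", {
  p <- scenario_params(chrom_lengths = c(chr1 = 2e6), n_loss = 30, seed = 1)
  expect_error(simulate_scenario(p), "cannot host")
})

test_that("noiseless tracks are exact step functions of the domain sets", {
  sc <- simulate_scenario(scenario_params(seed = 8))
  tr <- simulate_signal_tracks(sc, noise_params(sigma = 0, seed = 1))
  ref <- step_track(sc$assembly, sc$wt, 1, 0, 10000)
  expect_equal(tr$WT$rep1$values, ref$values)
  # closed pipeline identity: calling the noiseless track recovers WT
  called <- call_domains(tr$WT$rep1, caller_params(threshold = 0.5))
  expect_true(ladscape:::ds_equal(called, sc$wt))
})

test_that("replicates are distinct but share the planted mean structure", {
  sc <- simulate_scenario(scenario_params(seed = 12))
  tr <- simulate_signal_tracks(sc, noise_params(seed = 55))
  r1 <- unlist(tr$KO$rep1$values); r2 <- unlist(tr$KO$rep2$values)
  expect_false(identical(r1, r2))
  # per-replicate means over domain bins agree within 4*sigma/sqrt(n)
  inside <- unlist(step_track(sc$assembly, sc$ko, TRUE, FALSE, 10000)$values)
  n_in <- sum(inside)
  expect_lt(abs(mean(r1[inside]) - mean(r2[inside])),
            4 * 0.5 / sqrt(n_in) * sqrt(2))
  expect_lt(abs(mean(r1[inside]) - 1), 4 * 0.5 / sqrt(n_in))
})

test_that("gene simulation is stratified, non-overlapping and deterministic", {
  sc <- simulate_scenario(scenario_params(seed = 3))
  expect_equal(length(simulate_genes(sc, n_genes = 0)), 0L)
  g1 <- simulate_genes(sc, n_genes = 100, seed = 77, frac_gained = 0.4,
                       length_median = 8000)
  g2 <- simulate_genes(sc, n_genes = 100, seed = 77, frac_gained = 0.4,
                       length_median = 8000)
  expect_identical(g1$genes, g2$genes)

  # realized gained fraction is exact by construction
  st <- assign_gene_domain_status(g1, sc$truth)
  expect_equal(sum(st$gained), 40L)

  # transcripts never overlap
  df <- g1$genes[order(g1$genes$chrom, g1$genes$start), ]
  by_chr <- split(df, df$chrom)
  for (b in by_chr) {
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  # gene models are structurally valid (constructor re-validates)
  expect_s3_class(gene_set(g1$assembly, g1$genes, g1$exons), "GeneSet")
})

test_that("expression tables carry the planted downregulation effect", {
  sc <- simulate_scenario(scenario_params(seed = 4))
  genes <- simulate_genes(sc, n_genes = 120, seed = 21, frac_gained = 0.25,
                          length_median = 8000)

  # p_effect = 0 with default bounds: nothing passes the DE rule
  e0 <- simulate_expression(genes, sc, effect_params(p_effect = 0, seed = 1))
  de0 <- classify_de(e0)
  expect_true(all(de0$status == "ns"))

  # p_effect = 1, delta = 1: every gained-overlap gene is classified down
  e1 <- simulate_expression(genes, sc, effect_params(p_effect = 1, delta = 1,
                                                     seed = 2))
  de1 <- classify_de(e1)
  st <- assign_gene_domain_status(genes, sc$truth)
  expect_true(all(de1$status[st$gained] == "down"))
  expect_true(all(de1$status[!st$gained] == "ns"))

  # p_effect = 0.5: affected count within the Binomial 99% interval
  hits <- vapply(1:25, function(s) {
    e <- simulate_expression(genes, sc, effect_params(p_effect = 0.5, seed = s))
    sum(attr(e, "affected"))
  }, 1)
  n_gained <- sum(st$gained)
  bounds <- stats::qbinom(c(0.005, 0.995), n_gained, 0.5)
  expect_true(all(hits >= bounds[1] & hits <= bounds[2]))

  # planted in-LAD repression is visible in baseline expression
  res <- expression_by_lad(genes, sc$wt, e1)
  expect_lt(res$median_in, res$median_out)
})

test_that("write_scenario emits a loadable text bundle", {
  sc <- simulate_scenario(scenario_params(seed = 6))
  tr <- simulate_signal_tracks(sc, noise_params(seed = 2))
  genes <- simulate_genes(sc, n_genes = 30, seed = 3)
  ex <- simulate_expression(genes, sc, effect_params(seed = 4))
  dir <- withr::local_tempdir()
  write_scenario(sc, dir, tracks = tr, genes = genes, expression = ex)

  asm <- load_assembly(file.path(dir, "genome.chrom.sizes"))
  wt <- load_domains(file.path(dir, "WT.bed"), asm, merge_touching = FALSE)
  expect_true(ladscape:::ds_equal(wt, sc$wt))
  tr2 <- load_track(file.path(dir, "WT.rep1.bedgraph"), asm, bin_size = 10000)
  expect_equal(tr2$values, tr$WT$rep1$values)
  g2 <- load_genes(file.path(dir, "genes.tsv"), asm)
  expect_equal(g2$genes$gene_id, genes$genes$gene_id)
  e2 <- load_expression(file.path(dir, "expression.tsv"))
  expect_equal(e2$log2fc, ex$log2fc)
})
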