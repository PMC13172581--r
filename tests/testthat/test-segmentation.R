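# Domain calling, replicate merging, constitutive intersection, Venn.

test_that("call_domains segments threshold runs with gap and length rules", {
  asm <- toy_assembly(c(chrT = 1e5))
  tr <- binned_track(asm, 10000, list(chrT = c(0, 0, 0, 5, 5, 5, 5, 0, 0, 0)))
  d <- call_domains(tr, caller_params(threshold = 1, gap_bins = 0, min_bins = 1))
  expect_equal(as.data.frame(d), data.frame(chrom = "chrT", start = 30000, end = 70000))

  # all sub-threshold -> empty
  lo <- binned_track(asm, 10000, list(chrT = rep(0, 10)))
  expect_equal(length(call_domains(lo, caller_params(threshold = 1, min_bins = 1))), 0L)

  # gap bridging joins runs across one low bin
  asm5 <- toy_assembly(c(chrT = 5e4))
  g <- binned_track(asm5, 10000, list(chrT = c(5, 5, 0, 5, 5)))
  d2 <- call_domains(g, caller_params(threshold = 1, gap_bins = 1, min_bins = 1))
  expect_equal(as.data.frame(d2), data.frame(chrom = "chrT", start = 0, end = 50000))
  # without bridging the two runs stay apart
  d3 <- call_domains(g, caller_params(threshold = 1, gap_bins = 0, min_bins = 1))
  expect_equal(nrow(as.data.frame(d3)), 2L)

  # min length drops short runs
  d4 <- call_domains(tr, caller_params(threshold = 1, gap_bins = 0, min_bins = 5))
  expect_equal(length(d4), 0L)

  # missing bins break runs but are bridgeable
  na_tr <- binned_track(asm5, 10000, list(chrT = c(5, 5, NA, 5, 5)))
  d5 <- call_domains(na_tr, caller_params(threshold = 1, gap_bins = 1, min_bins = 1))
  expect_equal(as.data.frame(d5), data.frame(chrom = "chrT", start = 0, end = 50000))

  all_na <- binned_track(asm5, 10000, NULL)
  expect_error(call_domains(all_na), "missing")
})

test_that("quantile threshold mode uses non-missing values only", {
  asm <- toy_assembly(c(chrT = 1e5))
  v <- c(rep(0, 7), NA, 9, 10)
  tr <- binned_track(asm, 10000, list(chrT = v))
  # the 0.75 type-7 quantile of the 9 non-missing values {0 x7, 9, 10} is 0,
  # so every non-missing bin qualifies; the NA bin still breaks the run
  d <- call_domains(tr, caller_params(quantile = 0.75, gap_bins = 0, min_bins = 1))
  expect_equal(as.data.frame(d),
               data.frame(chrom = "chrT", start = c(0, 80000),
                          end = c(70000, 100000)))

  const <- binned_track(asm, 10000, list(chrT = rep(2, 10)))
  expect_warning(call_domains(const), "constant")
})

test_that("merge_replicates unions at base level", {
  asm <- toy_assembly()
  a <- ds1(asm, 0, 100); b <- ds1(asm, 50, 150)
  expect_equal(as.data.frame(merge_replicates(a, b)),
               data.frame(chrom = "chrT", start = 0, end = 150))
  # one replicate empty -> the other unchanged
  expect_true(ladscape:::ds_equal(merge_replicates(a, domain_set(asm)), a))
  # disjoint intervals stay apart
  m <- merge_replicates(ds1(asm, 0, 100), ds1(asm, 200, 300))
  expect_equal(length(m), 2L)
  # intersection mode for sensitivity analysis
  expect_equal(as.data.frame(merge_replicates(a, b, mode = "intersection")),
               data.frame(chrom = "chrT", start = 50, end = 100))
})

test_that("merge_replicates is commutative, associative and idempotent", {
  asm <- genome_assembly(c("chr1", "chr2"), c(2e5, 1e5))
  set.seed(11)
  for (i in 1:15) {
    a <- random_domain_set(asm); b <- random_domain_set(asm)
    cc <- random_domain_set(asm)
    expect_true(ladscape:::ds_equal(merge_replicates(a, b), merge_replicates(b, a)))
    expect_true(ladscape:::ds_equal(
      merge_replicates(merge_replicates(a, b), cc),
      merge_replicates(a, merge_replicates(b, cc))))
    expect_true(ladscape:::ds_equal(merge_replicates(a, a), a))
  }
})

test_that("consensus_intersection computes constitutive domains", {
  asm <- toy_assembly()
  a <- ds1(asm, 0, 100); b <- ds1(asm, 50, 150); cc <- ds1(asm, 75, 200)
  expect_equal(as.data.frame(consensus_intersection(list(a, b, cc))),
               data.frame(chrom = "chrT", start = 75, end = 100))
  # idempotence on identical sets
  expect_true(ladscape:::ds_equal(consensus_intersection(list(a, a, a)), a))
  # any empty input -> empty
  expect_equal(length(consensus_intersection(list(a, domain_set(asm)))), 0L)
  expect_error(consensus_intersection(list(a)), "at least 2")
  # monotone: adding sets never increases coverage
  set.seed(5)
  sets <- replicate(4, random_domain_set(asm), simplify = FALSE)
  cov2 <- coverage_bp(consensus_intersection(sets[1:2]))
  cov3 <- coverage_bp(consensus_intersection(sets[1:3]))
  cov4 <- coverage_bp(consensus_intersection(sets))
  expect_true(cov2 >= cov3 && cov3 >= cov4)
})

test_that("venn_coverage partitions the union into 7 exact regions", {
  asm <- toy_assembly()
  a <- ds1(asm, 0, 1e6)
  v <- venn_coverage(a, a, a)
  expect_equal(v$bp[v$region == "ABC"], 1e6)
  expect_equal(sum(v$bp[v$region != "ABC"]), 0)

  b <- ds1(asm, 50, 150)
  v2 <- venn_coverage(ds1(asm, 0, 100), b, domain_set(asm))
  got <- stats::setNames(v2$bp, v2$region)
  expect_equal(got[c("A.only", "AB", "B.only")], c(A.only = 50, AB = 50, B.only = 50))
  expect_equal(sum(got), 150)
})

test_that("venn_coverage agrees with the per-base membership oracle", {
  asm <- genome_assembly(c("chr1", "chr2"), c(6e4, 4e4))
  set.seed(99)
  for (i in 1:25) {
    a <- random_domain_set(asm, 8); b <- random_domain_set(asm, 8)
    cc <- random_domain_set(asm, 8)
    v <- venn_coverage(a, b, cc)
    oracle <- venn_bruteforce(a, b, cc)
    expect_equal(stats::setNames(v$bp, v$region), oracle)
    expect_equal(sum(v$bp), attr(v, "union_bp"))
  }
})

test_that("HMM caller recovers planted domains and handles degeneracy", {
  asm <- genome_assembly(c("chr1", "chr2"), c(1e7, 1e7))
  set.seed(3)
  sc <- simulate_scenario(scenario_params(seed = 3))
  # noiseless step: exact recovery of the planted set
  tr <- step_track(asm, sc$wt, 1, 0, 10000)
  d <- call_domains_hmm(tr)
  expect_true(ladscape:::ds_equal(d, sc$wt))
  # classic threshold caller recovers it too (threshold between levels)
  d2 <- call_domains(tr, caller_params(threshold = 0.5, gap_bins = 1, min_bins = 3))
  expect_true(ladscape:::ds_equal(d2, sc$wt))
  # constant track: warned, empty
  const <- binned_track(toy_assembly(c(chrT = 1e5)), 10000, list(chrT = rep(1, 10)))
  expect_warning(dc <- call_domains_hmm(const), "constant")
  expect_equal(length(dc), 0L)
})

test_that("average_tracks is the NA-aware bin-wise mean", {
  asm <- toy_assembly(c(chrT = 3e4))
  t1 <- binned_track(asm, 10000, list(chrT = c(1, NA, 3)))
  t2 <- binned_track(asm, 10000, list(chrT = c(3, 2, NA)))
  avg <- average_tracks(list(t1, t2))
  expect_equal(avg$values$chrT, c(2, 2, 3))
  t3 <- binned_track(asm, 10000, list(chrT = c(NA, NA, 1)))
  expect_equal(average_tracks(list(t1, t3))$values$chrT, c(1, NA, 2))
})
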