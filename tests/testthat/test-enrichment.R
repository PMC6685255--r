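test_that("shuffling preserves peak lengths, respects bounds, and is seeded", {
  set.seed(88)
  peaks <- random_peaks(300)
  sizes <- c(chr1 = 1e6, chr2 = 5e5)
  s1 <- shuffle_peaks(peaks, sizes, seed = 42)
  s2 <- shuffle_peaks(peaks, sizes, seed = 42)
  expect_identical(s1, s2)
  s3 <- shuffle_peaks(peaks, sizes, seed = 43)
  expect_false(identical(s1, s3))
  # multiset of lengths is conserved
  expect_equal(sort(s1$end - s1$start), sort(peaks$end - peaks$start))
  expect_true(all(s1$start >= 0))
  expect_true(all(s1$end <= sizes[s1$chrom]))
})

test_that("a peak as long as the only chromosome is placed at its start", {
  pk <- genomic_intervals("chr1", 100, 600, name = "full")
  s <- shuffle_peaks(pk, c(chrA = 500), seed = 1)
  expect_equal(c(s$chrom, s$start, s$end), c("chrA", "0", "500"))
  expect_error(shuffle_peaks(pk, c(chrA = 400)), "full")
})

test_that("chromosome choice is proportional to length (binomial oracle)", {
  pk <- genomic_intervals("chr1", 0, 100, name = "p")
  sizes <- c(big = 9e5, small = 1e5)
  n <- 10000
  s <- shuffle_peaks(pk[rep(1, n), ], sizes, seed = 7)
  frac_small <- mean(s$chrom == "small")
  p <- 1e5 / 1e6
  expect_lt(abs(frac_small - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("feature counts tally multi-feature peaks once per feature", {
  fx <- generate_fixture(fixture_spec(seed = 21))
  ann <- annotate_peaks(fx$peaks, fx, fx$expression)
  counts <- count_features(ann$records, ann$intergenic)
  for (f in c("Upstream", "5UTR", "Exon", "Intron", "3UTR", "Downstream"))
    expect_equal(counts[[f]], sum(ann$records[[f]]))
  expect_equal(counts[["Intergenic"]], nrow(ann$intergenic))
  zero <- count_features(ann$records[0, ], ann$intergenic[0, ])
  expect_true(all(zero == 0))
})

test_that("fold enrichment follows the observed/mean convention", {
  obs <- c(Upstream = 0, "5UTR" = 0, Exon = 50, Intron = 10, "3UTR" = 0,
           Downstream = 8, Intergenic = 0)
  sh <- lapply(c(20, 25, 30), function(k)
    c(Upstream = 0, "5UTR" = 0, Exon = k, Intron = 10, "3UTR" = 2,
      Downstream = 0, Intergenic = 0))
  fe <- fold_enrichment(obs, sh)
  expect_equal(fe$fold[fe$feature == "Exon"], 2.0)
  expect_equal(fe$fold[fe$feature == "Intron"], 1.0)   # identical counts
  expect_equal(fe$rand_sd[fe$feature == "Intron"], 0)
  expect_equal(fe$fold[fe$feature == "Upstream"], 1)   # both zero
  expect_equal(fe$fold[fe$feature == "Downstream"], Inf)  # null never hits
  expect_equal(fe$rand_mean[fe$feature == "Exon"], 25)
  expect_equal(fe$rand_sd[fe$feature == "Exon"], 5)
})

test_that("chi-squared closed forms and degenerate convention hold", {
  t0 <- chi2_feature_test(10, 10, 10, 10)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  t40 <- chi2_feature_test(20, 0, 0, 20)
  expect_equal(t40$statistic, 40)
  dg <- chi2_feature_test(0, 20, 0, 20)   # zero marginal
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 1)
})

test_that("chi-squared matches the reference implementation on random tables", {
  set.seed(99)
  for (i in 1:1000) {
    m <- matrix(sample(1:500, 4, replace = TRUE), 2)
    got <- chi2_feature_test(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("enrichment analysis is reproducible bit-for-bit under a seed", {
  fx <- generate_fixture(fixture_spec(seed = 14))
  e1 <- feature_enrichment(fx$peaks, fx, fx$expression, n_shuffles = 5,
                           seed = 77)
  e2 <- feature_enrichment(fx$peaks, fx, fx$expression, n_shuffles = 5,
                           seed = 77)
  expect_identical(e1$table, e2$table)
  expect_equal(e1$table$fold,
               e1$table$observed / e1$table$rand_mean)
})

test_that("real gene-body peaks enrich gene features and deplete intergenic space", {
  fx <- generate_fixture(fixture_spec(seed = 16))
  enr <- feature_enrichment(fx$peaks, fx, fx$expression, n_shuffles = 10,
                            seed = 3)
  tab <- enr$table
  expect_gt(tab$fold[tab$feature == "Exon"], 1.5)
  expect_lt(tab$fold[tab$feature == "Intergenic"], 0.7)
  expect_lt(tab$p_value[tab$feature == "Exon"], 0.01)
})
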