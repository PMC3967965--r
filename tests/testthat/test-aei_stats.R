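test_that("normalized allelic ratio is the cDNA ratio calibrated by gDNA", {
  expect_identical(
    normalized_allelic_ratio(aei_sample("s", 100, 50, 50, 50)), 2)
  expect_identical(
    normalized_allelic_ratio(aei_sample("s", 70, 30, 70, 30)), 1)
  expect_error(aei_sample("s", 100, 0, 50, 50), "positive")
  expect_error(aei_sample("s", 100, 50, -1, 50), "positive")
})

test_that("swapping allele labels inverts the normalized ratio exactly", {
  set.seed(12)
  for (rep in 1:25) {
    sig <- runif(4, 1, 200)
    a <- aei_sample("s", sig[1], sig[2], sig[3], sig[4])
    b <- aei_sample("s", sig[2], sig[1], sig[4], sig[3])
    expect_equal(normalized_allelic_ratio(a),
                 1 / normalized_allelic_ratio(b), tolerance = 1e-14)
  }
})

test_that("pyrosequencing ratios come from peak areas", {
  r <- pyro_allelic_ratio(60, 30)
  expect_identical(r$ratio, 2)
  expect_equal(r$percent_a, 200 / 3)
  expect_identical(pyro_allelic_ratio(50, 50)$ratio, 1)
  r0 <- pyro_allelic_ratio(10, 0)
  expect_true(r0$undefined)
  expect_identical(r0$percent_a, 100)
  expect_error(pyro_allelic_ratio(0, 0), "zero")
})

test_that("a perfectly balanced cohort gives p = 1 and ratio 1", {
  samples <- lapply(1:5, function(i) aei_sample(i, 80, 40, 60, 30))
  res <- aei_cohort_test(samples)
  expect_identical(res$mean_ratio, 1)
  expect_identical(res$p_vs_one, 1)
  expect_error(aei_cohort_test(samples[1:2]), "insufficient")
})

test_that("the paired t statistic matches the textbook formula on a toy", {
  samples <- list(aei_sample("a", 120, 50, 50, 50),
                  aei_sample("b", 95, 50, 52, 48),
                  aei_sample("c", 110, 60, 47, 51))
  res <- aei_cohort_test(samples)
  d <- vapply(samples, function(s)
    log2(s$ratio_cdna) - log2(s$ratio_gdna), 0)
  t_stat <- mean(d) / (sd(d) / sqrt(3))
  p_hand <- 2 * pt(-abs(t_stat), df = 2)
  expect_equal(res$p_paired, p_hand, tolerance = 1e-12)
  expect_equal(res$p_vs_one, p_hand, tolerance = 1e-12)
  expect_equal(res$mean_log2_ratio, mean(d))
})

test_that("the null cohort rejects at the nominal 5% rate", {
  hits <- vapply(1:1000, function(i) {
    cohort <- synth_aei_cohort(6, fold = 1, noise_cv = 0.1, seed = i)
    aei_cohort_test(cohort)$p_vs_one < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("a planted 2-fold imbalance is recovered with high confidence", {
  cohort <- synth_aei_cohort(22, fold = 2, noise_cv = 0.10, seed = 4)
  res <- aei_cohort_test(cohort)
  expect_lt(abs(res$mean_ratio - 2) / 2, 0.10)
  expect_lt(res$p_vs_one, 1e-4)
})

test_that("standard curves invert their dilution series", {
  quantity <- 10^(0:4)
  ct <- 30 - log10(quantity) * log2(10)  # efficiency exactly 2
  curve <- fit_standard_curve(quantity, ct)
  expect_equal(curve$slope, -log2(10))
  expect_equal(curve$efficiency, 2)
  expect_equal(quantify(ct, curve), quantity)
  expect_error(fit_standard_curve(c(1, 10), c(30, 27)), "at least 3")
  expect_warning(fit_standard_curve(quantity, rep(20, 5)), "degenerate")
  expect_equal(ct_to_quantity(1, 2), 0.5)
})

test_that("pearson correlation matches the closed-form computation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  y <- c(2.0, 1.0, 4.0, 3.5, 5.0)
  hand_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_correlation(x, y)
  expect_equal(res$r, hand_r, tolerance = 1e-12)
  t_stat <- hand_r * sqrt(3 / (1 - hand_r^2))
  expect_equal(res$p, 2 * pt(-abs(t_stat), df = 3), tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(1, 5)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})
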