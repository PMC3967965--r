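test_that("LD expansion is single-hop, strict, monotone and idempotent", {
  ld <- data.frame(snp_a = c("rsA", "rsB", "rsC"),
                   snp_b = c("rsB", "rsD", "rsE"),
                   r2 = c(0.9, 0.95, 0.8), stringsAsFactors = FALSE)
  expect_identical(expand_ld("rsA", NULL), "rsA")
  got <- expand_ld("rsA", ld)
  expect_setequal(got, c("rsA", "rsB"))           # single hop: no rsD
  expect_identical(expand_ld("rsC", ld), "rsC")   # r2 = 0.8 not > 0.8
  # monotone and idempotent
  expect_true(all(c("rsA") %in% got))
  expect_setequal(expand_ld(got, ld), c("rsA", "rsB", "rsD"))
  expect_setequal(expand_ld(expand_ld(got, ld), ld),
                  expand_ld(got, ld))
})

test_that("SNP membership uses half-open BED semantics", {
  track <- data.frame(chrom = "chr1", start = 10L, end = 20L,
                      stringsAsFactors = FALSE)
  snps <- data.frame(id = c("a", "b", "c", "d"),
                     chrom = c("chr1", "chr1", "chr1", "chr2"),
                     pos = c(10L, 19L, 20L, 15L), stringsAsFactors = FALSE)
  expect_identical(snps_in_track(snps, track), c(TRUE, TRUE, FALSE, FALSE))
  empty <- track[0, ]
  expect_identical(snps_in_track(snps, empty), rep(FALSE, 4))
})

test_that("interval membership matches the brute-force scan on random data", {
  set.seed(71)
  snps <- data.frame(id = paste0("s", 1:1000),
                     chrom = sample(c("chr1", "chr2"), 1000, TRUE),
                     pos = sample.int(5e4, 1000, TRUE) - 1L,
                     stringsAsFactors = FALSE)
  starts <- sample.int(5e4, 300, TRUE) - 1L
  track <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                      start = starts,
                      end = starts + sample.int(500, 300, TRUE),
                      stringsAsFactors = FALSE)
  expect_identical(snps_in_track(snps, track),
                   oracle_snps_in_track(snps, track))
})

test_that("the Venn tally counts both-members inside each margin", {
  tf <- data.frame(chrom = "chr1", start = c(0L, 100L), end = c(50L, 150L),
                   stringsAsFactors = FALSE)
  mir <- data.frame(chrom = "chr1", start = c(120L, 200L), end = c(160L, 240L),
                    stringsAsFactors = FALSE)
  snps <- data.frame(id = paste0("s", 1:5), chrom = "chr1",
                     pos = c(10L, 40L, 130L, 210L, 500L),
                     stringsAsFactors = FALSE)
  v <- overlap_venn(snps, tf, mir)
  expect_identical(v$n_snps, 5L)
  expect_identical(v$n_in_tf, 3L)
  expect_identical(v$n_in_mir, 2L)
  expect_identical(v$n_in_both, 1L)
  expect_identical(v$frac_in_both, 0.2)
  expect_lte(v$n_in_both, min(v$n_in_tf, v$n_in_mir))

  none <- overlap_venn(snps[5, , drop = FALSE], tf, mir)
  expect_identical(none$n_in_tf + none$n_in_mir + none$n_in_both, 0L)
})

test_that("binomial enrichment equals the direct tail sum", {
  expect_identical(binomial_enrichment(100, 0, 0.3)$p_binomial, 1)
  expect_equal(binomial_enrichment(5, 5, 0.5)$p_binomial, 0.5^5,
               tolerance = 1e-15)
  expect_identical(binomial_enrichment(50, 10, 1)$p_binomial, 1)
  set.seed(81)
  for (rep in 1:20) {
    n <- sample(1:2000, 1)
    k <- sample(0:n, 1)
    f <- runif(1)
    expect_equal(binomial_enrichment(n, k, f)$p_binomial,
                 pbinom(k - 1, n, f, lower.tail = FALSE), tolerance = 1e-12)
  }
  # large-n branch agrees with the exact sum at the boundary
  expect_equal(binomial_enrichment(20000, 150, 0.007)$p_binomial,
               pbinom(149, 20000, 0.007, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("the full report wires LD expansion, Venn and enrichment together", {
  tracks <- synth_tracks(genome_len = 2e5, n_tf = 20, n_mir = 12,
                         n_snps = 500, seed = 6)
  rep_ <- overlap_report(tracks$snps, tracks$ld, tracks$tf, tracks$mir,
                         tracks$genome_len)
  v <- rep_$venn
  expect_identical(v$n_snps, length(rep_$snp_ids))
  expect_lte(v$n_in_both, min(v$n_in_tf, v$n_in_mir))
  expect_true(all(vapply(rep_$enrichment, function(e)
    e$p_binomial >= 0 && e$p_binomial <= 1, logical(1))))
  # SNPs planted in shared regions make the "both" class strongly enriched
  expect_lt(rep_$enrichment$both$p_binomial, 1e-6)
})

test_that("site-level overlap fraction counts sites touching the other track", {
  sites <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L),
                      end = c(50L, 150L, 250L), stringsAsFactors = FALSE)
  track <- data.frame(chrom = "chr1", start = 140L, end = 210L,
                      stringsAsFactors = FALSE)
  expect_equal(sites_overlapping_track(sites, track), 2 / 3)
})
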