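test_that("the planted site generator round-trips through the scanner", {
  syn <- synth_transcript_with_site(utr_len = 600, flank = 300, seed = 21)
  sites_ref <- find_seed_sites(syn$mirna, syn$transcript)
  expect_identical(nrow(sites_ref), 1L)
  expect_true(sites_ref$start >= syn$site_start - 1L &&
                sites_ref$end == syn$site_end)
  t_alt <- apply_allele(syn$transcript, syn$variant, "alt")
  expect_identical(nrow(find_seed_sites(syn$mirna, t_alt)), 0L)
  # the variant sits inside the planted heptamer
  expect_identical(syn$variant$pos,
                   syn$site_start + 4L)  # default snp_offset_in_site = 5
})

test_that("generators are bit-stable under a fixed seed", {
  a <- synth_transcript_with_site(utr_len = 400, flank = 200, seed = 7)
  b <- synth_transcript_with_site(utr_len = 400, flank = 200, seed = 7)
  expect_identical(a$transcript$seq, b$transcript$seq)
  expect_identical(synth_aei_cohort(5, 2, 0.1, 13),
                   synth_aei_cohort(5, 2, 0.1, 13))
  expect_identical(synth_tracks(genome_len = 1e5, seed = 13),
                   synth_tracks(genome_len = 1e5, seed = 13))
  expect_identical(synth_correlated_series(50, -0.7, 13),
                   synth_correlated_series(50, -0.7, 13))
})

test_that("geometry violations are rejected", {
  expect_error(synth_transcript_with_site(utr_len = 100, flank = 98),
               "geometry")
  expect_error(synth_transcript_with_site(snp_offset_in_site = 0), "1-7")
  expect_error(synth_transcript_with_site(snp_offset_in_site = 8), "1-7")
})

test_that("noiseless cohorts carry the planted fold exactly", {
  cohort <- synth_aei_cohort(8, fold = 2.5, noise_cv = 0, seed = 1)
  ratios <- vapply(cohort, normalized_allelic_ratio, 0)
  expect_equal(ratios, rep(2.5, 8), tolerance = 1e-12)
})

test_that("track generator recovers its configured co-occurrence", {
  tracks <- synth_tracks(genome_len = 2e6, n_tf = 80, n_mir = 60,
                         n_snps = 10000,
                         co_occurrence = c(tf = 0.15, mir = 0.05, both = 0.05),
                         seed = 17)
  v <- overlap_venn(tracks$snps, tracks$tf, tracks$mir)
  # 3 binomial standard errors at n = 10000
  se <- function(p) 3 * sqrt(p * (1 - p) / 10000)
  expect_lt(abs(v$frac_in_both - 0.05), se(0.05))
  expect_lt(abs(v$frac_in_tf - 0.20), se(0.20))    # tf-only + both
  expect_lt(abs(v$frac_in_mir - 0.10), se(0.10))   # mir-only + both

  disjoint <- synth_tracks(genome_len = 2e6, n_snps = 2000,
                           co_occurrence = c(tf = 0, mir = 0, both = 0),
                           seed = 18)
  v0 <- overlap_venn(disjoint$snps, disjoint$tf, disjoint$mir)
  expect_identical(v0$n_in_tf + v0$n_in_mir + v0$n_in_both, 0L)
})

test_that("correlated series hit their target correlation", {
  exact <- synth_correlated_series(20, -1, seed = 2)
  expect_equal(pearson_correlation(exact$x, exact$y)$r, -1)
  big <- synth_correlated_series(1e4, -0.7, seed = 2)
  expect_lt(abs(pearson_correlation(big$x, big$y)$r - (-0.7)), 0.02)
})

test_that("fixture directories are written readably and reproducibly", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_dir(d1, seed = 5, utr_len = 400, aei_n = 5,
                    genome_len = 2e5)
  write_fixture_dir(d2, seed = 5, utr_len = 400, aei_n = 5,
                    genome_len = 2e5)
  for (f in c("utr.fa", "variants.tsv", "aei.tsv", "tf.bed", "mir.bed",
              "snps.tsv", "ld.tsv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_no_warning({
    utr <- read_fasta(file.path(d1, "utr.fa"))
    v <- read_variants(file.path(d1, "variants.tsv"))
    read_aei_table(file.path(d1, "aei.tsv"))
    read_bed(file.path(d1, "tf.bed"))
    read_snp_table(file.path(d1, "snps.tsv"))
    read_ld_table(file.path(d1, "ld.tsv"))
  })
  check_variant(utr[[1]], v[[1]])
})
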