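test_that("the default moving-segment grid enumerates 90 windows per allele", {
  syn <- synth_transcript_with_site(utr_len = 2000L, flank = 1053L, seed = 3)
  w <- enumerate_windows(syn$transcript, syn$variant)
  expect_identical(nrow(w), 90L)
  expect_identical(as.integer(table(w$size)[c("100", "200", "400", "800")]),
                   c(10L, 20L, 20L, 40L))
  # snp sits at snp_offset within each window
  expect_true(all(w$start + w$snp_offset - 1L == syn$variant$pos))
  expect_true(all(w$end - w$start + 1L == w$size))
})

test_that("window counts follow sum(floor(size/step)) for arbitrary schemes", {
  t <- transcript("t", strrep("A", 3000))
  v <- variant("t", 1500, "A", "G")
  expect_identical(nrow(enumerate_windows(t, v, window_scheme(100, 50))), 2L)
  set.seed(31)
  for (rep in 1:15) {
    k <- sample(1:3, 1)
    sizes <- as.integer(sample(seq(20, 120, by = 10), k))
    steps <- sample(10:25, k, replace = TRUE)
    w <- enumerate_windows(t, v, window_scheme(sizes, steps))
    expect_identical(nrow(w), as.integer(sum(sizes %/% steps)))
  }
})

test_that("windows that would leave the transcript are errors, not clipped", {
  t <- transcript("t", strrep("A", 900))
  v <- variant("t", 850, "A", "G")
  expect_error(enumerate_windows(t, v), "outside transcript")
})

test_that("both alleles are folded over identical coordinates, deterministically", {
  syn <- synth_transcript_with_site(utr_len = 300L, flank = 140L, seed = 5)
  scheme <- window_scheme(c(60L, 80L), c(20L, 20L))
  ens <- fold_ensemble(syn$transcript, syn$variant, scheme)
  expect_identical(nrow(ens$windows), 7L)
  expect_length(ens$structures$ref, 7L)
  expect_length(ens$structures$alt, 7L)
  for (i in seq_len(7)) {
    sref <- ens$structures$ref[[i]]$seq
    salt <- ens$structures$alt[[i]]$seq
    diff <- which(strsplit(sref, "")[[1]] != strsplit(salt, "")[[1]])
    expect_identical(diff, ens$windows$snp_offset[i])
  }
  ens2 <- fold_ensemble(syn$transcript, syn$variant, scheme)
  expect_identical(lapply(ens$structures$ref, `[[`, "dotbracket"),
                   lapply(ens2$structures$ref, `[[`, "dotbracket"))
})

test_that("snp context summary counts loops and stems coherently", {
  # unstructured background: the SNP can never pair
  t <- transcript("t", strrep("A", 200))
  v <- variant("t", 100, "A", "C")
  ens <- fold_ensemble(t, v, window_scheme(40L, 20L))
  s <- snp_context_summary(ens)
  expect_identical(s$n_loop + s$n_stem, s$n_windows)
  expect_identical(s$fraction_loop, c(1, 1))

  # planted perfect stem through the SNP: window is GGGGAAAACCCC with the
  # variant base the final C, which the MFE fold must pair
  seq <- paste0(strrep("A", 88), "GGGGAAAACCCC", strrep("A", 100))
  t2 <- transcript("t2", seq)
  v2 <- variant("t2", 100, "C", "G")
  ens2 <- fold_ensemble(t2, v2, window_scheme(12L, 12L))
  s2 <- snp_context_summary(ens2)
  expect_identical(s2$fraction_loop[s2$which == "ref"], 0)

  # consistency identity: fractions equal a direct recount via pair_context
  syn <- synth_transcript_with_site(utr_len = 300L, flank = 140L, seed = 8)
  ens3 <- fold_ensemble(syn$transcript, syn$variant,
                        window_scheme(c(60L, 100L), c(20L, 25L)))
  s3 <- snp_context_summary(ens3)
  for (which in c("ref", "alt")) {
    ctx <- vapply(seq_len(nrow(ens3$windows)), function(i)
      pair_context(ens3$structures[[which]][[i]],
                   ens3$windows$snp_offset[i]), character(1))
    expect_identical(s3$fraction_loop[s3$which == which],
                     mean(ctx != "stem"))
  }
})

test_that("site accessibility is the unpaired fraction of the site", {
  open <- secondary_structure(strrep("A", 20), NULL)
  expect_identical(site_accessibility(open, 5, 11), 1)
  hp <- mfe_fold("GGGGAAAACCCC")
  expect_identical(site_accessibility(hp, 1, 4), 0)
  expect_equal(site_accessibility(hp, 3, 9), 4 / 7)
  expect_error(site_accessibility(hp, 0, 5), "outside")
})

test_that("probing concordance applies Pb and T1 chemistry rules", {
  open <- secondary_structure(strrep("A", 10), NULL)
  pb <- data.frame(allele = "C", position = c(2, 5), reagent = "Pb",
                   strength = "strong", stringsAsFactors = FALSE)
  res <- probing_concordance(open, pb)
  expect_identical(res$fraction, 1)

  t1_bad <- data.frame(allele = "C", position = 3, reagent = "T1",
                       strength = "weak", stringsAsFactors = FALSE)
  res2 <- probing_concordance(open, t1_bad)
  expect_identical(res2$records$verdict, "invalid")
  expect_identical(res2$n_total, 0L)

  expect_error(probing_concordance(open, pb, window_offset = 8), "outside")
})

test_that("the packaged cleavage table scores to the hand tally", {
  cl <- read_cleavage_table(cleavage_fixture_path())
  expect_identical(nrow(cl), 14L)
  # window 1040-1075 (offset 1039), all unpaired, G residues at the T1 spots
  bases <- rep("A", 36)
  bases[c(1054, 1058, 1070) - 1039] <- "G"
  open <- secondary_structure(paste(bases, collapse = ""), NULL)

  resC <- probing_concordance(open, cl[cl$allele == "C", ], 1039)
  expect_identical(resC$n_total, 6L)       # six Pb records
  expect_identical(resC$n_concordant, 6L)  # all unpaired

  resG <- probing_concordance(open, cl[cl$allele == "G", ], 1039)
  expect_identical(resG$n_total, 8L)       # 5 Pb + 3 T1, all on valid residues
  expect_identical(resG$n_concordant, 8L)

  # pairing the 1058-1063 run flips exactly the C-allele Pb records there
  paired <- secondary_structure(
    paste(c(rep("A", 18), "GGGGGG", rep("A", 4), "CCCCCC", rep("A", 2)),
          collapse = ""),
    cbind(19:24, 34:29))
  resC2 <- probing_concordance(paired, cl[cl$allele == "C", ], 1039)
  expect_identical(resC2$n_concordant, 0L)
})
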