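test_that("explicit structures score by loop decomposition", {
  model <- energy_model()
  expect_identical(energy_of_structure("ACGUACGUA", NULL), 0)

  helix <- cbind(c(1, 2, 3, 4), c(12, 11, 10, 9))
  hand <- 3 * model$stack["GC", "GC"] + model$hairpin[4]
  expect_equal(energy_of_structure("GGGGAAAACCCC", helix), hand)

  expect_error(
    energy_of_structure("GGGGGAAAACCCCC", cbind(c(1, 2), c(10, 14))),
    "crossing")
  expect_error(energy_of_structure("GCAAGC", cbind(1, 5)),
               "non-canonical|hairpin")
  expect_error(energy_of_structure("GAAAC", cbind(1, 4)), "hairpin")
})

test_that("short or unpairable sequences fold to the open chain at zero", {
  s <- mfe_fold("AAAAAAAAAA")
  expect_identical(s$dotbracket, "..........")
  expect_identical(s$energy, 0)
  expect_identical(mfe_fold("GCGC")$dotbracket, "....")
  expect_identical(mfe_fold("GCGC")$energy, 0)
})

test_that("the DP minimum matches exhaustive enumeration at small sizes", {
  expect_equal(mfe_fold("GGGGAAAACCCC")$energy, oracle_mfe("GGGGAAAACCCC"))
  expect_identical(mfe_fold("GGGGAAAACCCC")$dotbracket, "((((....))))")

  # exhaustive over every length-6 sequence, random at 8-12
  for (code in 0:(4^6 - 1)) {
    digits <- (code %/% 4^(0:5)) %% 4
    seq <- paste(c("A", "C", "G", "U")[digits + 1], collapse = "")
    expect_equal(mfe_fold(seq)$energy, oracle_mfe(seq), tolerance = 1e-9)
  }
  set.seed(202)
  for (rep in 1:80) {
    seq <- random_rna(sample(8:12, 1))
    expect_equal(mfe_fold(seq)$energy, oracle_mfe(seq), tolerance = 1e-9)
  }
})

test_that("constrained folds match the constrained enumeration oracle", {
  set.seed(203)
  for (rep in 1:40) {
    n <- sample(8:12, 1)
    seq <- random_rna(n)
    cons <- sort(sample(n, sample(0:n, 1)))
    got <- mfe_fold(seq, constraints = cons)
    expect_equal(got$energy, oracle_mfe(seq, cons), tolerance = 1e-9)
    expect_true(all(got$partner[cons] == 0L))
  }
})

test_that("forcing positions unpaired never lowers the energy", {
  set.seed(204)
  for (rep in 1:15) {
    seq <- random_rna(sample(20:60, 1))
    free <- mfe_fold(seq)$energy
    cons <- sort(sample(nchar(seq), sample(1:8, 1)))
    expect_gte(mfe_fold(seq, constraints = cons)$energy, free - 1e-9)
  }
})

test_that("every returned structure re-scores identically and is valid", {
  set.seed(205)
  for (rep in 1:10) {
    seq <- random_rna(sample(30:80, 1))
    s <- mfe_fold(seq)
    expect_equal(energy_of_structure(seq, s$pairs), s$energy,
                 tolerance = 1e-9)
    # determinism
    expect_identical(mfe_fold(seq)$dotbracket, s$dotbracket)
  }
})

test_that("pair_context labels stems and each loop class", {
  hp <- mfe_fold("GGGGAAAACCCC")    # ((((....))))
  expect_identical(pair_context(hp, 2), "stem")
  expect_identical(pair_context(hp, 6), "hairpin_loop")

  # internal loop: (((..(((...)))..))) style built explicitly
  seq_int <- "GGGAAGGGAAACCCAACCC"
  s_int <- secondary_structure(
    seq_int, cbind(c(1, 2, 3, 6, 7, 8), c(19, 18, 17, 14, 13, 12)))
  expect_identical(pair_context(s_int, 4), "internal_or_bulge")

  # multiloop with two hairpin branches, plus exterior bases
  seq_ml <- "AAGGGGAAACCCGGGAAACCCCAA"
  pairs_ml <- cbind(c(3, 4, 5, 6, 13, 14, 15),
                    c(22, 12, 11, 10, 21, 20, 19))
  s_ml <- secondary_structure(seq_ml, pairs_ml)
  expect_identical(pair_context(s_ml, 1), "exterior")
  expect_identical(pair_context(s_ml, 23), "exterior")
  expect_identical(pair_context(s_ml, 4), "stem")
  expect_identical(pair_context(s_ml, 8), "hairpin_loop")
})

test_that("dot-bracket parsing and rendering are inverse", {
  set.seed(206)
  for (rep in 1:10) {
    s <- mfe_fold(random_rna(40))
    expect_identical(partner_to_dotbracket(dotbracket_to_partner(s$dotbracket)),
                     s$dotbracket)
  }
  expect_error(dotbracket_to_partner("(()"), "unbalanced")
})
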