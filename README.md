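# mirallele

Allele-specific microRNA target-site and regulatory-variant analysis in R.

## The problem

A single-nucleotide variant in a 3′-UTR can sit inside a microRNA seed
match and rewire post-transcriptional regulation: one allele pairs
perfectly with the miRNA seed (guide nt 2–8) and is repressed, the other
carries a seed mismatch and escapes. The canonical example this package is
built around is a coronary-disease-associated C>G variant in a bHLH
transcription factor's 3′-UTR, where the major C allele completes a
`GUGACUU` heptamer complementary to miR-224 and the minor G allele breaks
it. Deciding whether such a variant is functional takes several
independent lines of computation, and `mirallele` implements each as a
tested, reusable module:

- **Seed scanning** (`find_seed_sites`, `allelic_site_effect`): canonical
  site taxonomy (8mer > 7mer-m8 > 7mer-A1 > 6mer), Watson–Crick only in
  the seed, scored per allele.
- **RNA secondary structure** (`mfe_fold`, `energy_of_structure`,
  `pair_context`): minimum-free-energy folding under a compact
  nearest-neighbor model (Zuker-style dynamic programming in C++, no
  pseudoknots, optional forced-unpaired constraints), with an explicit
  loop-decomposition scorer that the DP must agree with.
- **Moving-window ensembles** (`window_scheme`, `fold_ensemble`,
  `snp_context_summary`): the variant is folded inside windows of
  100/200/400/800 nt that slide across it in 10–20-nt steps — 90 windows
  per allele, 180 structures for the C/G pair — and classified loop vs
  stem in each.
- **Binding energetics** (`duplex_energy`, `site_open_penalty`,
  `site_ddG`): ΔΔG = ΔG_duplex + ΔG_open, i.e. hybridization energy of
  the guide:site duplex plus the cost of freeing the site from local
  structure (`ΔG_open = E(constrained fold) − E(free fold) ≥ 0`).
- **Structure probing concordance** (`probing_concordance`): Pb²⁺ cleaves
  any unpaired residue, RNase T1 only unpaired G — predicted structures
  are scored against cleavage tables under exactly those rules.
- **Annealing kinetics** (`fraction_complexed`, `estimate_kobs`):
  irreversible second-order association A + B → AB in closed form, and
  single-parameter least-squares recovery of k_obs (M⁻¹s⁻¹) from
  fraction-complexed time courses.
- **Allelic expression imbalance** (`normalized_allelic_ratio`,
  `aei_cohort_test`): per-sample cDNA/gDNA allelic-ratio normalization
  and paired/one-sample t-tests on log2 ratios.
- **Genome-track overlap** (`expand_ld`, `overlap_venn`,
  `binomial_enrichment`): LD-proxy expansion (r² strictly above a
  threshold, single hop), SNP × TF-track × miRNA-track Venn counts, and
  GREAT-style binomial region enrichment against a genome background.
- **Synthetic data** (`synth_*`, `write_fixture_dir`): seeded generators
  for every input class, so the whole pipeline is testable offline.

## Worked example

```r
library(mirallele)

mir224 <- mirna("miR-224", "CAAGUCACUAGUGGUUCCGUU")
utr    <- transcript("toy-utr", paste0(strrep("A", 20), "GUGACUU", strrep("A", 20)))
v      <- variant("toy-utr", 25, "C", "G", "rs12190287")

find_seed_sites(mir224, utr)
#>   mirna_id transcript_id site_type start end t1_pos
#> 1  miR-224       toy-utr      8mer    21  27     28

allelic_site_effect(mir224, utr, v)
#> <allelic site effect miR-224 x toy-utr@25C>G>: ref_match=TRUE alt_match=FALSE -> disrupted_by_alt

allelic_ddG(utr, v, mir224, 11, 37, 21, 27, region = "seed")[c("ref", "alt")]
#> $ref  <duplex_result allele C: dG_duplex=-7.86 dG_open=0.00 ddG=-7.86 kcal/mol>
#> $alt  <duplex_result allele G: dG_duplex=-2.74 dG_open=0.00 ddG=-2.74 kcal/mol>

tc <- simulate_timecourse(2.2e6, A0 = 0.5e-9, B0 = 5e-9, noise_cv = 0.05, seed = 42)
estimate_kobs(tc)
#> <rate_estimate: k_obs = 2.28e+06 /M/s, sse = 0.000624, converged = TRUE>

aei_cohort_test(synth_aei_cohort(n = 22, fold = 2, noise_cv = 0.10, seed = 1))$mean_ratio
#> [1] 2.07215
```

Reading: the C allele completes an 8mer site for miR-224 at 21–27 that
the G allele destroys (`disrupted_by_alt`); the C-allele duplex is about
5 kcal/mol more favorable than the mismatched G duplex (both sites fully
accessible here, so ΔΔG equals ΔG_duplex); a noisy annealing time course
generated at k = 2.2×10⁶ M⁻¹s⁻¹ is re-estimated within a few percent; and
a 22-sample cohort with a planted 2-fold imbalance is recovered at ≈2.07.

A full end-to-end replay on a seeded synthetic system — truth table,
180-window ensemble, ΔΔG, probing concordance, kinetics, AEI, expression
correlation and overlap enrichment in one report — is

```r
replay_tcf21(seed = 1)            # list; ~1-2 min (180 MFE folds)
```

or, from a shell, `inst/cli/mirallele replay --seed 1 --out report.json`
(add `--fast` to skip the ensemble). The same CLI exposes `scan`, `fold`,
`ddg`, `ensemble`, `probe`, `kinetics-fit`, `aei`, `overlap` and
`simulate` subcommands over files.

## Documentation

Every exported function carries roxygen documentation, and the methods
vignette (`vignettes/allele-specific-mirna-targeting.Rmd`) describes the
models, parameter choices, numerical conventions and limitations.
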