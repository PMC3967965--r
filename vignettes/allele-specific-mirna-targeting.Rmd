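---
title: "Methods: allele-specific miRNA targeting analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific miRNA targeting analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirallele)
```

`mirallele` asks one question from several directions: does a
single-nucleotide variant inside a 3′-UTR change how a microRNA engages
that transcript? This vignette records the models behind each module, the
parameters that matter, the numerical conventions, and what the test
suite does and does not establish.

## Coordinates and alphabets

Transcript positions are 1-based and inclusive, counted from the 5′ end,
because that is how positions inside a UTR are reported in practice
(e.g. "the variant at position 1058"). Genomic intervals use the BED
convention, 0-based half-open, because that is what BED files mean. A SNP
occupies the single genomic base `[pos, pos + 1)`. All sequence input is
normalized to uppercase RNA (`T` becomes `U`) on entry; anything outside
`ACGTUacgtu` plus whitespace is rejected with the offending position
rather than silently coerced.

## Seed scanning

A canonical site is an exact Watson–Crick reverse complement of the
guide seed on the transcript. Four site types are recognized with the
usual hierarchy — 8mer (seed nt 2–8 matched plus an A opposite nt 1),
7mer-m8 (nt 2–8), 7mer-A1 (nt 2–7 plus the A anchor), 6mer (nt 2–7) —
and each matched locus reports only its best type. Two deliberate
choices:

* **No G:U wobble in the seed.** The allelic question is whether a C:G
  pair becomes a G:G mismatch; admitting wobble would blur exactly the
  contrast being measured.
* **Truncated 3′ ends.** A site whose nt-1 position would fall past the
  transcript end can still be a 7mer-m8 or 6mer, never an 8mer or
  7mer-A1, since the anchor base does not exist.

`allelic_site_effect` scans both allele sequences and restricts to sites
whose seed interval contains the variant. The verdict is
`disrupted_by_alt` / `created_by_alt` / `unaffected` from the
(ref-match, alt-match) pair; when neither allele has a site at the
variant, the verdict distinguishes `unaffected` (the miRNA has sites
elsewhere) from `absent` (it has none at all), which keeps the common
"variant far from any site" case from reading like a missing site.

## The energy model and MFE folding

Folding uses a compact nearest-neighbor model shipped as a plain-text,
versioned parameter table (`inst/extdata/nn_params_v1.tsv`): stacking
free energies for Watson–Crick and G:U pairs (kcal/mol at 37 °C),
tabulated hairpin/bulge/internal-loop length penalties with logarithmic
extrapolation beyond 30 nt (coefficient 1.08 kcal/mol), an affine
multiloop term (offset 3.4, 0.4 per branch, 0.1 per unpaired base) and a
duplex initiation penalty of 4.09 kcal/mol. Simplifications relative to
full modern parameterizations, chosen so that the dynamic program and an
exhaustive enumeration oracle provably optimize the same function:

* no dangling ends, no coaxial stacking, no terminal-AU penalties,
  no sequence-dependent loop bonuses;
* bulge and internal loops scored by total length only (a 1×1 mismatch
  is an internal loop of size 2);
* lonely pairs allowed; minimum hairpin loop 3 nt.

Absolute energies from this table are therefore not comparable to any
specific external folding engine, and nothing in the package treats them
as such: all conclusions rest on orderings (which allele binds better,
paired vs unpaired) and on internal consistency, which the tests enforce
by comparing `mfe_fold` against brute-force enumeration over every valid
structure at small sizes, with and without constraints.

The DP is the standard pseudoknot-free recursion (paired matrix,
multiloop segment matrix, exterior suffix array), implemented in C++ for
the 800-nt windows. Interior loops are capped at 30 unpaired nt total,
standard practice that bounds the interior search; the R scorer has no
such cap, so DP/enumeration agreement is guaranteed where optimal
interior loops stay within the cap — always true at the oracle sizes.
Equal-energy ties are broken deterministically: the traceback re-derives
decisions in a fixed scan order preferring the pairing with the smallest
5′ index, then the smallest 3′ index, so identical inputs always return
identical structures. Sequences shorter than 5 nt cannot pair and return
the open chain at 0 kcal/mol, which is also the energy reference: the
all-unpaired structure scores exactly zero, and exterior bases are free.

Forced-unpaired constraints simply remove every pair touching a
constrained position from the search space. Constrained optima can never
beat unconstrained ones, which is both tested as a property and used as
the definition of accessibility cost below.

## Window ensembles

`window_scheme()` defaults to sizes 100/200/400/800 nt with steps
10/10/20/20 nt; each size slides so the variant sits at every multiple of
the step inside the window, giving `floor(size/step)` = 10+20+20+40 = 90
windows per allele and 180 folded structures for an allele pair. The
published description of this design fixes the sizes and the step range
but not the exact per-size grid; this grid is pinned as the package
default because it reproduces the stated ensemble size while staying
inside the stated step range, and it is fully configurable. Windows that
would run past the transcript are errors rather than being clipped:
silently unequal windows would break the paired per-window comparison
between alleles, which always uses identical transcript coordinates.

The per-window classification of the variant base is binary — `stem` if
paired, `loop` otherwise — with hairpin, internal/bulge, multiloop and
exterior contexts all counted as loop, since the downstream summary is a
loop/stem dichotomy. The finer `pair_context` label is retained in
`ensemble_report` for anyone who wants the breakdown.

## Accessibility and ΔΔG

The binding score per allele is `ΔΔG = ΔG_duplex + ΔG_open`.
`ΔG_duplex` is the nearest-neighbor energy of the antiparallel
guide:site hybrid (stacks over consecutive pairs, symmetric internal
loops for mismatches, free overhangs, one initiation term; a hybrid with
no possible pair returns 0 — no duplex). `ΔG_open` is the cost of
constraining the whole site unpaired in the window's MFE structure,
non-negative by construction. This open-cost-penalized convention makes
a matched, accessible site strongly negative and a mismatched or buried
site less favorable, reproducing the qualitative allelic sign pattern; a
quantitative match to any particular published ΔΔG number is explicitly
out of scope because such numbers are energy-model-dependent. The duplex
region defaults to the full site but can be restricted to the seed
heptamer (`region = "seed"`), which is the right choice when flanking
pairing should not dilute the seed contrast.

## Probing concordance

Pb²⁺ cleavage reports any unpaired residue; RNase T1 reports unpaired
G residues only. `probing_concordance` scores a predicted window
structure against a cleavage table under exactly those rules, flagging
T1 records on non-G residues as invalid and excluding them from the
denominator rather than counting them as discordant — they are evidence
about the record, not the structure. The packaged cleavage table
(`cleavage_fixture_path()`) carries the per-allele cleavage positions
around the C/G variant; cleavage strength is carried through but not
weighted in the concordance fraction, since the binary paired/unpaired
prediction has no graded counterpart in this model.

## Annealing kinetics

The annealing model is irreversible second-order association,
`dx/dt = k (A0 − x)(B0 − x)`, solved in closed form and evaluated in an
overflow-safe parameterization (the exponential is always of a
non-positive argument). Irreversibility is appropriate because the
read-out fits association-only rate constants for complexes that are
stable on the measurement timescale. The default sampling grid is 10,
30, 60, 120, 300, 600, 1200 s — a log-spaced grid spanning the approach
to plateau at the default concentrations (labeled strand 0.5 nM, target
5 nM, tenfold excess); the published experiment does not print its
sampling times, so this grid is a package choice. `estimate_kobs` is a
single-parameter least-squares fit on the fraction scale (not
linearized, so plateau points are not overweighted), searched over
log10(k) within k ∈ [10², 10¹⁰] M⁻¹s⁻¹ with the initial-slope estimate
`k ≈ (df/dt)/B0` as the starting point. All-zero or non-finite
time courses are rejected as unfittable rather than returning a boundary
value.

## Allelic imbalance statistics

Each heterozygous sample is normalized by its own genomic DNA:
`(a_cDNA/b_cDNA)/(a_gDNA/b_gDNA)`, so assay-specific allele bias cancels
per sample and the no-imbalance expectation is exactly 1. Cohort tests
run on log2 ratios because allelic ratios are multiplicative; the paired
t-test (cDNA vs gDNA log-ratios) and the one-sample t-test (normalized
log-ratio vs 0) are both reported, two-sided. A cohort in which every
normalized ratio is identical has zero paired variance; the degenerate
t statistic is resolved directly (p = 1 at ratio 1, p = 0 otherwise)
instead of erroring. Ct inputs convert to quantities as
`efficiency^(−Ct)` or through a fitted standard curve (OLS of Ct on
log10 quantity; a slope ≥ 0 warns as degenerate).

## Overlap enrichment

LD expansion is a single hop: partners with r² strictly greater than the
threshold (default 0.8) join the set, with no transitive closure —
standard proxy-SNP practice, and idempotent by construction. Overlap
membership uses half-open interval semantics via interval trees
(IRanges), with an O(n·m) brute-force oracle in the tests. The
enrichment p-value is the exact binomial upper tail
`P(X ≥ k), X ~ Bin(n, f)` with `f` the annotation's fraction of the
background genome, summed term by term for n ≤ 10⁴ and computed from the
stable upper-tail routine above that. The background fraction for the
joint TF∩miR class is taken as the product of the two coverages, i.e.
independence of the two annotations under the null.

## Synthetic data: what it emulates, what it does not

All generators derive their RNG streams from one root seed through a
fixed counter scheme (`substream_seed`), so outputs are bit-stable and
adding a generator never changes existing fixtures. Defaults mirror the
study conditions: a 2000-nt UTR with the heptamer planted so the variant
sits at position 1058, a 22-sample heterozygous cohort with 2-fold cDNA
imbalance and 10% multiplicative noise, annealing courses at 0.5/5 nM,
a 16-point expression series with target correlation −0.7, and toy
genome tracks with configurable SNP co-occurrence fractions (defaults
15% TF-only, 5% miR-only, 5% both — chosen as a desk-scale regime where
all Venn classes are well populated, not as an estimate of genome-wide
rates).

The generators are deliberately idealized: uniform base composition
(configurable GC only), exact planted signals, independent lognormal
noise, disjoint rectangular genome regions, no real LD structure and no
ENCODE-like peak-length distributions. Passing tests therefore establish
that each algorithm recovers what its model assumes — not that real
UTRs are unstructured outside the site, that real cohorts have lognormal
noise, or that genome-scale counts from public catalogs would be
reproduced. The genome-scale overlap numbers in particular require
external track downloads and are structurally, not numerically, mirrored
here.

## Numerical conventions

* Energies compare at 10⁻⁹ kcal/mol in tests; the DP/scorer consistency
  check inside `mfe_fold` uses 10⁻⁶.
* The closed-form kinetics agree with adaptive ODE integration to 10⁻⁶
  in fraction units (tested).
* Report JSON emits numerics at 6 significant digits for diffability;
  replay with the same seed is byte-identical.
* Every validator rejects rather than repairs: reference-allele
  mismatches, out-of-bounds windows, crossing pairs, sub-3-nt hairpin
  loops, malformed table lines (with line numbers) are all errors.

## Problem sizes used by the test suite

The suite exercises: exhaustive structure enumeration for every
length-6 sequence and random sequences up to length 12 (with and without
constraints); the full 180-window ensemble on a 2000-nt transcript;
10⁴ SNPs × 10³ intervals for the overlap oracle; 100-replicate
noise-recovery and 1000-replicate type-I-error simulations for kinetics
and AEI. These sizes were chosen so each statistical check has enough
replication to be meaningful while the whole suite stays comfortably
runnable on a laptop.

## Known limitations

* No partition function or base-pair probabilities; accessibility is a
  binary MFE statement, not an ensemble probability.
* No pseudoknots, dangles, coaxial stacks or special-loop corrections;
  absolute folding energies are not portable across energy models.
* Duplex alignment is positionally fixed (guide k against site L−k+1);
  bulged duplexes are approximated by symmetric internal loops.
* Annealing ignores dissociation and any structural rearrangement
  mechanism; k_obs is an effective constant for the modeled reaction.
* The AEI module starts from allele signals; raw fluorescence traces and
  pyrogram base-calling are out of scope.
* LD is consumed as a table; the package does not compute r² from
  genotypes.
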