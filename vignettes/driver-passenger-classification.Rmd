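---
title: "Classifying somatic point mutations as putative drivers or passengers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying somatic point mutations as putative drivers or passengers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverpass)
```

## The problem and the modelling idea

Tumours accumulate thousands of somatic single-nucleotide variants (SNVs).
A small minority are *drivers* — variants under positive selection that
contribute to tumour growth — while the vast majority are *passengers* that
hitch-hike along. Catalogued cancer variants come with a *recurrence* count
`r`: the number of independent tumour samples in which the identical variant
was observed. driverpass operationalises driver/passenger discrimination
purely from cancer data via recurrence:

* **positives** (putative drivers): variants with `r >= rho`, where the
  default thresholds are `rho = 7` in coding and `rho = 8` in non-coding
  regions;
* **negatives** (putative passengers): singleton variants (`r = 1`), but
  only those lying within a matching window `w` of some positive on the same
  chromosome (`w = 10000` nt coding, `w = 1000` nt non-coding). Window
  matching forces the two classes to live in comparable genomic
  neighbourhoods, so a classifier cannot win simply by recognising broad
  genomic location;
* variants with `1 < r < rho` are excluded from training but retained on a
  side channel so that relabeling at other thresholds (recurrence sweeps)
  needs no re-parsing.

A binary kernel classifier is then trained on feature groups describing each
variant's genomic context and evaluated with leave-one-chromosome-out
cross-validation (LOCO-CV): each autosome in turn is held out as the test
set, the other autosomes train the model, and X, Y and mitochondrial
variants never enter either side. LOCO-CV guards against position-linked
leakage that a random split would permit.

## Feature groups

Seven groups are computed per variant, each a row-aligned numeric matrix:

| Group | Content | Key parameter (default) |
|---|---|---|
| Conservation | per-position values of conservation-style score tracks | track list |
| GC | G+C fraction around the variant | window 100 nt |
| Uniqueness | per-position uniqueness-style track values | track list |
| LocalMutFreq | somatic variants within a region around the position | region width 1000 nt |
| GeneProximity | distance to nearest TSS / splice site / TFBS / CDS | log1p-transform on |
| Spectrum | normalized k-mer frequencies of the reference window | k = 3, window 100 nt |
| FunctionalElements | overlap indicators per functional-element class | class list |

Conventions that the tests freeze:

* windows of width `w` are centred as `[pos - floor(w/2), pos + ceil(w/2) - 1]`
  and clipped at chromosome ends;
* the mutation-frequency region of 1000 positions is read as ±500 around the
  variant, excluding the variant itself;
* proximity distance is 0 when the position overlaps an interval and the
  nucleotide distance to the nearer interval boundary otherwise; distances
  are log1p-transformed by default because raw distances span orders of
  magnitude and the monotone transform preserves ranking while taming the
  kernel geometry;
* k-mers containing N are skipped; an all-N window yields a missing value;
* conservation and uniqueness are consumed as input tracks (bedGraph), never
  recomputed from alignments.

Missing feature values are imputed with column means estimated **from
training rows only** (`assemble_features(..., train_idx = )`), matching the
train-only standardization below; a leakage test asserts that perturbing
held-out rows changes no imputation or standardization statistic.

## The classifier

All selected groups are concatenated into a single design matrix and fed to
one kernel — the single-kernel route lets the model learn interactions
between features from different sources. The learner is a regularized kernel
machine: after per-column standardization (population SD; constant columns
get SD 1), the dual coefficients solve

$$(K + \lambda I)\,\alpha = y, \qquad y_i \in \{-1, +1\},$$

with an RBF kernel whose bandwidth defaults to the median heuristic (median
pairwise training distance — data-adaptive and deterministic) and
$\lambda = 1$. Decision values are mapped to $[0,1]$ scores by a monotone
sigmoid (Platt) calibration fitted on the training decision values with the
usual regularized targets, so downstream logic only ever sees calibrated
scores. The hard label is "+" iff score ≥ 0.5 (ties positive; scores below
0.5 are negative). The exact learner behind the published scores is not
specified in the available text; this package's kernel machine is a
conventional realization of the single-kernel contract, and every
downstream component depends only on the `[0,1]`-score interface. The fit is
fully deterministic: no step draws random numbers.

*Cautious classification*: confidence is the score's distance from 0.5. At
cutoff `tau` (> 0.5), predictions are high-confidence iff score ≥ `tau` or
score ≤ 1 − `tau`; coverage is the fraction of high-confidence examples and
cautious metrics are computed over those only. Coverage is provably
non-increasing in `tau`; under well-calibrated scores cautious accuracy at
high `tau` should not fall below the default accuracy (both are asserted on
synthetic runs).

## Forward feature-group selection

Groups are first ranked by mean LOCO balanced accuracy as singletons (ties
keep the declared group order). Starting from the top-ranked group, each
round adds every remaining group to the current set as one concatenated
kernel, takes the best addition, and accepts it only if its paired per-fold
improvement is significant. All candidates in a round share the fold
partition and the per-fold subsampling seed, so comparisons are paired.

Two stop rules are provided, since the published criterion is not stated in
the available text:

* `"stderr"` (default, the simplest conventional choice): accept when the
  mean paired improvement exceeds one standard error of the per-fold
  differences;
* `"permutation"`: a paired sign-flip test (exact enumeration up to 12
  folds), with the significance level Bonferroni-corrected by the number of
  candidates examined in the round. The correction matters: testing only the
  best of m candidates inflates the false-acceptance rate of the naive test
  roughly m-fold, and our pilot calibration showed the one-SE rule accepting
  pure-noise groups in a large fraction of rounds (P(t > 1) ≈ 0.2 per
  candidate before selection bias). Experiments that need a calibrated
  false-acceptance rate — including the selection-recovery checks in the
  test suite — use the permutation rule with eight simulated autosomes so the
  exact sign-flip distribution has 2^8 atoms.

The returned trace records, per round, the candidate added, per-fold
accuracies, mean accuracy, the accept/reject verdict with its reason, and a
single stopping reason; re-evaluating any step's group set under the same
seed reproduces its recorded accuracies exactly.

## The synthetic-data generator

`sim_config()` / `simulate_study()` generate a complete study: a
uniform-composition genome over `n_chroms` autosomes, planted
CDS/TSS/splice-site/TFBS annotation, functional elements in two classes,
standard-normal score tracks (two conservation-like, one uniqueness-like)
binned at 25 nt, and a somatic catalog in which each of `n_drivers`
hotspots hosts one recurrent variant (`r` from a truncated geometric on
`[rho_sim, r_max]`, defaults `[7, 20]`) and `n_passengers` singletons are
placed 70/30 within/beyond the matching window of a hotspot, so window
matching has true positives and true negatives to filter.

Class-conditional effects are expressed in SD units of the baseline feature
distribution and planted mechanistically per group: track effects add the
configured shift to bins in the hotspot core (radius 150 nt; passengers are
kept at least 200 nt from hotspot centres so they sit outside the core); the
GC effect re-draws core bases with a shifted G+C probability scaled so one
unit ≈ one SD of the 100-nt GC feature; the Spectrum effect plants `ACG`
motif copies in the core; GeneProximity and FunctionalElements effects plant
a TSS (or an element) near a fraction of hotspots. Options:

* `effect_by_r` widens the recurrence support to `[2, r_max]` and scales
  each hotspot's effect by `(r − 1)/(r_max − 1)` — the recurrence-sweep
  test bed, where balanced accuracy should rise with the labeling threshold
  until the positive class collapses;
* `effect_split` assigns the Conservation and Uniqueness effects to
  complementary hotspot halves, so either group alone explains only half the
  drivers — the forward-selection test bed (with additive same-hotspot
  effects, adding the second group improves accuracy too little relative to
  fold noise to be reliably detected);
* `germline_mode` adds a germline-like cohort placed beyond hotspot
  neighbourhoods while somatic neighbourhoods (radius `w`) are shifted by
  `germline_contrast` SD, emulating the observation that rare somatic
  variants sit in more conserved, more mutation-dense regions than germline
  variants; `distribution_test()` (two-sample Kolmogorov–Smirnov by
  default, Wilcoxon by option) detects the planted shift, reporting
  underflowing p-values as an analytic upper bound (e.g. `< 1e-120`), never
  as 0.

Everything is deterministic under `seed` (byte-identical FASTA included).

**What the generator does not emulate.** Real mutational signatures,
subclonal structure, chromatin covariates, and the scale/composition of real
catalogs are all out of scope; features are conditionally independent given
hotspot placement, which real data are not. Passing tests therefore
demonstrate that the pipeline's machinery is correct and well-calibrated,
not that any particular accuracy will transfer to real cancer catalogs.

**A structural caveat worth knowing.** In a hotspot-clustered design, local
mutation density is informative about the driver class even with all effect
sizes at zero, because drivers sit at the centres of passenger clusters.
This is a faithful property of recurrence-clustered catalogs, not a bug; but
it means zero-effect null calibrations must exclude the LocalMutFreq group
(the test suite's null runs use the five track/sequence groups:
Conservation, Uniqueness, GC, Spectrum, GeneProximity; we measured a
singleton balanced accuracy of ≈ 0.69 for LocalMutFreq under a zero-effect
null versus ≈ 0.5 for every other group).

## Numerical and design choices

* **Coordinates.** Internally everything is 1-based closed (GRanges);
  BED/bedGraph half-open coordinates are converted at the format boundary by
  rtracklayer, VCF positions pass through unchanged. Window-match distance
  `|pos_neg − pos_pos| ≤ w` is inclusive; matching is per-chromosome.
* **Chromosome names** are normalized at ingest ("1" ≡ "chr1",
  "MT" ≡ "chrM").
* **Standardization** uses the population SD convention; constant columns
  store SD 1 (warned) and become all-zero.
* **Degenerate folds** (empty or single-class training side) are skipped
  with a warning and their test rows reported unscored; metrics with a zero
  denominator are `NA`, never 0.
* **Subsampling** (balanced 4000 + 4000 by default, as in the published
  protocol) runs under a private seeded RNG stream per fold (`seed + fold`),
  isolated from the global random state, so runs are reproducible
  independent of call order.
* **Score-track overlaps** resolve last-wins with a read-time warning; the
  missing-track-value marker is `NA` (a sentinel like −1 would collide with
  legitimately negative conservation scores).

## Problem sizes used by the test suite

The packaged experiments are desk-scale by design: the signal-recovery and
null-calibration studies use 4 simulated autosomes of 100 kb with 150
drivers and 2650 passengers (a labeled dataset of ≈ 2000 variants, balanced
training subsets of 150 per class); selection-recovery uses 8 autosomes of
50 kb with 240 drivers and 1400 passengers over 10 seeds per scenario; the
recurrence sweep spans `rho` 2–10 with effects scaling linearly in `r`.
These sizes give the acceptance properties comfortable statistical margins
(verified by pilot power calculations) while keeping the whole suite a
few minutes long on one CPU.

## Known limitations

* The kernel solve is dense O(n³): training sets beyond ~10⁴ examples per
  fold need subsampling (the default protocol already subsamples to 4000 per
  class).
* Recurrence counts are taken at face value from the input; per-patient
  deduplication and liftover between genome builds are out of scope.
* The two stop rules for forward selection are documented substitutes for an
  unpublished criterion; their selected sets can differ on marginal signal.
* Calibration is a single global sigmoid; no per-chromosome recalibration is
  attempted.
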