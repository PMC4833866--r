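---
title: "Models and methods behind gisscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gisscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gisscreen)
```

This vignette explains the models implemented in `gisscreen`, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The screen and its scoring model

A GCR patch test grows a patch of a strain and replica-plates it onto
medium that only cells having lost both counter-selectable markers can
survive. Every papilla on the selective plate descends from an independent
rearrangement event that occurred while the patch grew. The semi-
quantitative score bins the papillae count: 0 (none), 1 (1–5, the typical
control patch), 2 (6–15), 3 (16 up to a countable ~150), 4 (too many to
count), 5 (a lawn). The GCR strain score is the arithmetic mean of the
valid patch scores of one genotype in one assay; at least three
independent spore clones are scored in practice. Patches that failed to
grow are represented as an `NA` sentinel rather than a numeric value so
they can never leak into a mean; a strain whose patches all failed is
flagged undefined and ignored downstream.

Two numerical choices are ours: the score-3/score-4 boundary is fixed at
150 papillae and the lawn threshold at 1,000 counts (both configurable) —
the upper bands are defined qualitatively at the bench, and deterministic
boundaries are needed for reproducible simulation. `strain_score()` warns
rather than fails below three valid patches because real screens
occasionally yield fewer clones.

## The synthetic screen generator

`simulate_screen()` draws, for every strain and patch, the number of
pre-plating GCR events as Poisson with mean `m = rate × cells_per_patch`.
The per-assay wild-type rates (6e-11, 1e-9, 8e-9 events per cell division
for the sGCR-, dGCR- and tyGCR-like assays, at 2×10^9 effective cells per
patch) were calibrated once so the control strain reproduces typical
published control scores (≈0.1, ≈0.9, ≈2.7) and were not revisited.

The default papillae model is Poisson on the *event count*. A
fluctuation-style alternative (`model = "jackpot"`) additionally expands
each event into a Lea–Coulson clone of size `⌊1/U⌋` and reports total
mutant cells, which produces the classic jackpot tails of fluctuation
assays. We made Poisson the default for two reasons. Biologically, the
cells of one pre-plating clone are colocated in the patch, so a jackpot
lineage tends to appear as one (or few) papillae, not as hundreds: the
papillae count tracks the number of independent events more closely than
the number of mutant cells. Statistically, the jackpot model's tails give
patch-score distributions so heavy that strain-score differentials of 0.4
arise in ~10% of null pairs at six patches per strain, which is
inconsistent with the operating characteristics the differential rule is
known to have; the event-count model reproduces them.

Effect structure: a fraction (default 0.15, close to the hit rate of a
candidate-enriched screen) of non-query baits are planted GIS genes with
rate folds drawn log-normally (median 10, sdlog 0.5); each planted bait
expresses its fold in any given assay with probability 0.7, producing the
imperfect cross-assay overlap real mutants show. Query mutations get folds
with median 1 (sdlog 0.4): a query panel is chosen to sensitise without
saturating the assay — cooperating mutations often cause no rate increase
alone, and strains with high single-mutant scores yield few detectable
interactions. Double-mutant rates follow the multiplicative null
`wt × fold_query × fold_bait`, times a planted `synergy_fold` (default 10)
for a random 10% of unordered pairs — about the fraction one obtains from
~13% of doubles being called at ~71% validation. Cross failures are
strain-level: with probability 0.05 a strain contributes no patches at
all. The control strain is scored from more patches (default 12 vs 4)
because controls are replicated across plates and the control score
anchors the calling cutoff; an under-replicated mid-scale anchor inflates
false calls in the high-rate assay.

The generator does **not** emulate: plate/batch effects, human scoring
disagreement, suppressor mutations accumulating in double mutants (a real
source of validated-rate false positives), assay-specific rearrangement
spectra, or correlated folds within complexes. Passing tests therefore
demonstrate correctness of the analysis machinery under a clean generative
model, not robustness to those real-data phenomena.

## Cutoff optimisation and the discrete KS test

With rate folds paired to scores, mutants at rate fold ≥ 3 form the
positive class. One consistent decision rule is used — call positive iff
score ≥ c — so the four confusion counts partition the data (the
alternative of using a strict inequality for false positives only would
leave boundary pairs double-counted or dropped). The cost
`w1·SENS + w2·SPEC` is evaluated on the candidate grid of midpoints
between consecutive distinct observed scores plus sentinels beyond the
extremes; a data-derived grid is the natural reading of published optima
that are not round numbers. Ties in cost are broken toward the lowest
cutoff, favouring sensitivity, consistent with the default weights
(`w1 = 2, w2 = 1`) whose rationale is that false positives are cheap to
remove by follow-up rate measurement.

Patch scores live on a six-point support, so the classical KS null is
wrong. `ks_discrete_test()` computes the supremum ECDF distance over the
pooled support and obtains its null by permuting the pooled sample, which
conditions on the observed ties; the p-value is the add-one rank
`(k + 1)/(n_mc + 1)`, never exactly zero. A parametric discrete null would
require knowing the patch-score distribution; permutation does not.

## GIS, interactions, modules

GIS calling flags genes scoring ≥ `delta` (default 0.4) above the per-assay
measured control score; we anchor on the measured control rather than a
rounded common baseline because the assays differ widely in their control
scores. Measured rate folds then override scores in both directions, and a
prior-literature list is unioned in last. Interactions use the same 0.4
differential against the higher of the two single-mutant scores; calls
with any score at or above 4.5 carry a saturation flag (high-scoring
singles crowd the top of the scale and their differentials are
unreliable) but are retained. Reciprocal crosses are reported separately,
never averaged. cGIS genes are called baits minus GIS genes. A module is
group 1 when at least two members have called interactions sharing a
common query; modules with no tested member are marked untested rather
than group 2. The optional rate-based confirmation of a called
interaction defaults to a greater-than-additive criterion
(`double fold > fold_a + fold_b`), with the multiplicative null available;
greater-than-additive is the weaker and more inclusive reading of a
"synergistic increase", and the choice is exposed.

## Cancer-side classification

Candidate genes are selected by S-score (a precomputed integrated
tumour-suppressor signature) at ≤ −2, with the borderline band to −1.95
included but reported distinctly; proto-oncogene signatures (≥ 2) are
selectable with the flipped sign but carried no further. Defect
categories per sample × gene: any loss-of-function mutation; missense
with `ndamage` ≥ 5 of 6; GISTIC −1/−2 with expression Z < −2; and
silencing, fixed here as hypermethylation with Z < −2 **and no copy loss**
(GISTIC ≥ 0) — no numeric silencing rule is standard, and requiring
diploid copy number isolates epigenetic loss from copy-number-driven loss
(configurable). Categories whose platform a sample lacks are `NA`
(unassessed), never `FALSE`; the summary denominator defaults to samples
with any platform data, with a complete-data denominator available, and an
MMR-gene sample-exclusion hook supports hypermutator-free reanalysis.

## Randomisation tests

Both enrichment tests use 10,000 random sets by default and the add-one
one-sided rank p-value — "ranking the real set in the random distribution"
made exact, with no zero p-values. The S-score test draws same-size sets
uniformly without replacement. The mutation test draws genes without
replacement until the cumulative protein length reaches the query set's
total; the last gene may overshoot, the mean overshoot fraction is
reported, and no rescaling is applied — this is the simplest reading of
matching by total amino acids, and the overshoot makes the test very
slightly conservative (the random sets are marginally longer than the
real one). The naive same-size test is exposed as `match_by = "count"`
purely for comparison: with length-proportional background mutation it
inflates the type-I error several-fold on length-biased sets, which is the
reason the length normalisation exists.

## Problem sizes and numerical conventions

The package's own verification runs at desk scale, chosen as the smallest
sizes at which the statistical properties are informative: screens of 200
baits × 10 queries (six patches per strain for operating-characteristic
checks, pooled over several replicate screens because a single noisy
query-single estimate biases all of that query's differentials), null
calibrations of 1,000 simulated datasets with a few hundred permutations
each, and cohorts of a few hundred samples. Published full-scale counts
that depend on the original strain collection and cohort extracts (e.g.
total gene tallies) are not reproducible at these sizes and are not
asserted; printed worked examples (score bands, pair combinatorics, the
completeness extrapolation) are asserted exactly.

Conventions: all seeds are explicit and fix every output byte; p-values
use the add-one rank; degenerate inputs (no positives, empty samples,
strains with no valid patches, samples with no platform data) error or
flag early with informative messages rather than propagating NaNs.

## Known limitations

The generator's clean Poisson world understates real patch-score noise
sources (batch effects, scorer variability, suppressors), so real-screen
precision for the 0.4-differential rule will be lower than simulated
precision — published rate validation of called interactions suggests
~70% rather than ~85–90%. The score scale saturates near 4–5, and no
correction for saturation is attempted beyond flagging. The cancer-side
rules are threshold classifications, not statistical models: no
uncertainty is attached to per-sample calls, and the silencing rule is a
fixed convention. The length-matched permutation treats the mutation
table as fixed, so it conditions on the observed mutation burden and does
not model between-cohort variability.
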