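---
title: "Integrative species delimitation with specdelim: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative species delimitation with specdelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdelim)
```

## The problem

Cryptic radiations of direct-developing frogs (such as the Andean
*Pristimantis*) hide substantial species-level diversity behind conserved
external morphology. `specdelim` implements the integrative-taxonomy workflow
used to resolve such groups: candidate lineages are first proposed from
mitochondrial (16S) distance data, then confirmed or rejected by asking
whether independent character sets — morphometrics, advertisement calls,
environmental occupancy — covary with the genetic splits, and finally each
accepted species is given an IUCN criterion-B conservation assessment from
its occurrence records.

This vignette documents the models and the conventions behind each stage,
the tunable parameters that matter, what the synthetic-data generators do
and do not emulate, and the numerical choices an analyst should know about.

## Genetic distances and candidate lineages

The genetic unit of analysis is the **uncorrected p-distance**: the
proportion of differing nucleotide sites between two aligned sequences,
with **pairwise deletion** — a site is dropped for a pair whenever either
sequence carries anything outside `{A, C, G, T}` (gaps, `N`, `?`, IUPAC
ambiguity codes). Treating ambiguity codes as missing rather than as
partial matches is the dominant convention of distance software and keeps
the estimator exactly equal to a site-counting oracle; a pair with no
comparable site gets a missing distance, not an error.

Group summaries (`group_distance_summary()`) report arithmetic means of the
pairwise distances within and between clades, in percent. Standard errors
come from a **site bootstrap**: alignment columns are resampled with
replacement (default `n_boot = 1000`, seed mandatory) and the group means
recomputed per replicate; the SE is the standard deviation across
replicates. A statistic that is constant across sites therefore has SE 0,
and SEs shrink roughly as the inverse square root of alignment length.

Candidate lineages are found by **single-linkage threshold clustering** of
the *group-mean* matrix (`identify_candidates()`): two groups merge
whenever their mean distance is strictly below the threshold, and merging
chains. Three choices deserve emphasis:

* the default threshold is **0.02** (2%) of uncorrected 16S distance — the
  value at which sister candidate species in these frogs are still
  separable, below the 3% barcoding-gap convention for amphibians;
* the comparison is **strict** (`< threshold`): a pair of clades at exactly
  2.0% stays distinct, which is the only reading consistent with using 2.0%
  as the reference divergence between valid species;
* clustering operates on group means, not on sequence-level linkage,
  because published divergence tables — and the transcribed table shipped
  in `inst/extdata/` — are phrased in group means.

`identify_candidates()` is monotone: raising the threshold can only merge
clusters, never split them.

## Morphometrics

Five standard measurements (SVL, HL, HW, TD, ED; mm) are analyzed per sex,
adults only. `descriptive_stats()` reports `mean ± SD; min–max` with the
sample (n−1) SD, omitting the SD for n = 1.

**Size correction** regresses each variable on SVL by OLS, pooled across
species within each sex. Pooling is deliberate: fitting per species would
absorb the between-species shape differences into the fits, whereas pooled
residuals retain exactly the signal the pairwise tests are meant to detect.
Residuals of the fitted rows are orthogonal to SVL and sum to zero by
construction.

**Pairwise tests** use the two-sample Wilcoxon–Mann–Whitney rank-sum
statistic on the residuals. The literature on this group reports a
"Wilcoxon signed-rank" Z for independent species samples; the two-sample
rank-sum statistic is the only coherent reading, and is what is
implemented. `Z` is the tie-corrected standardized statistic without
continuity correction (antisymmetric under swapping groups). The p-value is
exact by enumeration of all label arrangements when the combined sample
size is at most 12; beyond that the normal approximation is used *with* a
0.5 continuity correction — without it the approximation misstates
two-sided tail probabilities by up to 0.02 even at 15 per group, which we
verified against the exact rank-sum distribution. Batch comparisons are
Holm-adjusted by default (`adjust = "none"` reproduces unadjusted
reporting).

**Discriminant classification** (`discriminant_classify()`) is a linear
discriminant analysis on the raw (uncorrected) measurements with pooled
within-group covariance and proportional priors, scored by
**resubstitution**: the fitted classifier re-predicts its own training
specimens. Resubstitution (rather than cross-validation) matches the
"classification assigned the correct species" phrasing of classical
reports and the default of the statistics packages they used; it is
optimistically biased, which is why a chance-level data set scores
somewhat above 1/k. The reported rate is `100 * trace(confusion) / n`.

## Advertisement-call acoustics

`call_features()` measures the ten standard per-call parameters: notes per
call, number of harmonics, note duration, inter-note interval (missing for
single-note calls), peak time, dominant frequency, second-harmonic
frequency, initial and final frequency, and frequency change (final −
initial, an identity that holds exactly as computed).

Conventions and parameters:

* **Segmentation** works on the magnitude of the analytic signal smoothed
  by a 5 ms moving average; regions above 10% of the envelope maximum are
  notes, gaps shorter than 20 ms are bridged, and detections shorter than
  20 ms are dropped. Thresholds are relative, so segmentation is invariant
  to recording gain.
* **Spectra** use a fixed 4096-point DFT at 44.1 kHz, i.e. 10.77 Hz bins —
  the frequency resolution bracket of the original Raven analyses. The
  dominant frequency is the argmax of a Welch-style averaged power
  spectrum (Hann windows of up to 4096 samples, hop of one eighth of a
  window). Averaging matters: a single whole-note periodogram of a long
  frequency sweep carries Fresnel ripple that can displace the argmax by
  more than a bin, while the averaged spectrum of a symmetric-envelope
  sweep peaks at the mid-sweep frequency to within a bin.
* **Initial/final frequency** are estimated from a short-time spectral-peak
  track (25 ms frames) fitted by a straight line and extrapolated to the
  note boundaries. A naive spectral peak over the first/last 25 ms would
  sit near the *center* of that window and bias a linear sweep's endpoints
  by half a window of sweep each side (plus more when the envelope skews
  the window); the track-and-extrapolate estimator is exact for linear
  sweeps and reduces to the windowed peak for constant tones. The window
  length is configurable (`edge_window_s`); the source analyses do not
  state one.
* **Harmonics** are counted as spectral peaks within ±2 bins of integer
  multiples of the (parabolically interpolated) fundamental exceeding the
  dominant peak minus 30 dB. The −30 dB floor is explicit configuration:
  the visual criterion used in spectrogram-based counts is unrecoverable.
* **Peak time** is the envelope argmax within the note. For the
  raised-cosine notes of this group it sits at the note midpoint; under
  added noise the envelope top is flat enough that the argmax can wander a
  few milliseconds.

No statistical comparison of calls across species is provided: with two
recordings per species the original analyses could not test differences,
and neither do we.

## Environmental analysis

Occurrence records are **spatially thinned** before analysis: conspecific
localities closer than 10 km (twice the 5 km buffer radius) are linked
into connected components and one random representative per component is
retained (seeded). Component-wise thinning avoids the order dependence of
greedy sequential rules; localities of different species never interact.
Distances are great-circle (haversine) on a 6371 km sphere — at a 10 km
rule the difference from a planar GIS buffer is negligible.

The 11 environmental variables (8 bioclimatic + GPP, LAI, NDVI; mixed
units) enter a **correlation-matrix PCA**: correlation rather than
covariance is forced by the mixed units and by the fact that the published
eigenvalues sum to 11. Components with eigenvalue > 1 are retained (Kaiser
criterion). Loadings are principal-component loadings — eigenvector times
the square root of the eigenvalue — matching the magnitudes of published
loading tables (raw unit eigenvectors could not reach 0.956); each
column's sign is fixed so its largest-magnitude loading is positive.
Scores are centered with variance equal to the eigenvalue (n−1
convention).

The pipeline deliberately stops at exposing per-species score
distributions. Whether environmental "differentiation" supports a split is
left as an analyst flag to the delimitation stage, because the source
workflow judged it by inspection of the score plot, not by a formal test.
Raster extraction is out of scope: the variable matrix is an input.

## Range metrics and Red List categorization

**EOO** is the area of the 2-D convex hull after projecting the points to
a Lambert azimuthal equal-area plane centered on their centroid (6371 km
sphere); fewer than three non-collinear points give 0. **AOO** counts
occupied cells of a fixed-origin 2 × 2 km grid in the same projection,
times 4 km². The grid origin sits at the projection center; IUCN permits
origin optimization (minimizing occupied cells), which is not implemented.

`assess_category()` applies criterion B: B1 thresholds on EOO (CR < 100,
EN < 5000, VU < 20000 km²) and B2 on AOO (CR < 10, EN < 500, VU < 2000
km²), each requiring at least two of the conditions *a* (few locations),
*b(iii)* (continuing habitat decline) and *c* (extreme fluctuations).
"Locations" in the IUCN sense are threat-defined and cannot be computed
from coordinates, so the count is an analyst input, and condition *a* is
taken as satisfied at 10 or fewer locations — the reading consistent with
published assessments that assign CR B1ab(iii) to species known from two
locations. A degenerate EOO of 0 never triggers B1 (the assessment falls
through to AOO), `data_deficient` short-circuits to DD, NT is never
emitted automatically, and anything that misses the thresholds or the
two-condition rule is LC. Shrinking EOO or AOO while holding the flags
fixed can never lower the threat category.

## Delimitation rules

Each candidate lineage carries a genetic flag (nearest-neighbour mean
distance above the threshold or not) and three character states in
`{divergent, not_divergent, unavailable}`:

| genetic > threshold | characters | status |
|---|---|---|
| no | — | conspecific |
| yes | all unavailable | UCS (unconfirmed candidate) |
| yes | ≥ 1 divergent | CCS (confirmed candidate) |
| yes | available, none divergent | DCL (deep conspecific lineage) |

The 54 possible evidence states map to exactly one status each. Character
covariation is an expert judgment in the source workflow, so manual flags
are the primary path; `morphology_flag()` offers one explicit rule-based
convention (divergent when at least one variable has adjusted p < 0.05
against every neighbour) for analysts who want reproducible flags.

## The synthetic-data generators

Every stage can be exercised offline through seeded generators whose
defaults are the study conditions:

* `simulate_alignment()` evolves a random root along a star topology under
  JC69 with group-specific branch lengths (default length 1300 sites, the
  16S fragment scale). The expected p-distance between groups at total
  separation *d* is the closed form `3/4 (1 − exp(−4d/3))`; at d = 0.05
  that is ≈ 0.0484, which simulation recovers within Monte-Carlo error. A
  star topology is sufficient because only distances, not tree shape,
  feed the threshold logic; model curvature beyond JC69 is irrelevant to
  *uncorrected* distances.
* `simulate_morphometrics()` draws SVL from a truncated normal per species
  and sex (scale calibrated to adult sizes of ~20–45 mm SVL) and builds
  each variable as `slope · SVL + offset + noise`.
* `synthesize_call()` builds notes as linear frequency sweeps with
  harmonics under a raised-cosine envelope. Durations, gaps and sweep
  endpoints refer to the **audible** note — the region above the 10%
  detection threshold, which is what an oscillogram measurement delimits —
  so the raised-cosine support is stretched by
  `1 / (1 − 2·acos(1 − 2·thr) / 2π)` and the sweep is anchored at the
  threshold crossings. Without this convention a raised-cosine note is
  detected ~20% shorter than its support and no segmentation could
  reproduce the nominal duration.
* `simulate_localities()` scatters points around cluster centers on the
  local tangent plane; `simulate_env()` draws multivariate-normal rows
  with species mean shifts. The default environmental correlation is
  block-structured (temperature variables 1–5, precipitation 6–8,
  vegetation 9–11 correlated at 0.6 within blocks, independent across)
  because that is the structure real bioclimatic layers show — and the
  structure the published loading table reflects in its separate
  temperature, vegetation and precipitation components. A single global
  common factor would leak unshifted variables into PC1 and blur
  group separation in a way real layers do not.

What the generators do **not** emulate: rate variation among sites and
lineages, base-composition bias, coalescent gene-tree noise, juvenile or
allometrically nonlinear morphology, reverberant or wind-contaminated
field recordings, and spatial sampling bias. Tests passing on synthetic
data therefore validate the *measurement and decision machinery*, not the
field difficulty of acquiring clean inputs.

## Numerical choices and degenerate inputs

* Percent distances are rounded only at report time (1 decimal in the
  table writers); internal arithmetic is full precision.
* Bootstrap and all generators require an explicit seed; identical
  configuration and seed give byte-identical artifacts (timestamps are
  confined to the run log).
* Zero comparable sites → missing distance; silent recording → zero
  notes; a note shorter than the edge window, an empty morphometric
  table, a constant environmental variable, zero SVL variance, or a
  missing between-group mean raise informative errors naming the
  offending record, variable or pair.
* Singular pooled covariance in the discriminant analysis is reported
  with the variable set rather than silently regularized.
* Problem sizes used in the test suite (alignments of 2–10 sequences ×
  50–1300 sites, 50-replicate JC69 recovery, 100–200-replicate
  Monte-Carlo envelopes, one synthesized call per published parameter
  row) were chosen to give stable statistical checks at interactive
  runtimes.

## Known limitations

* EOO/AOO values of the original study are not reproducible here: they
  depend on the study's unpublished supplementary coordinates and on the
  internals of the GIS workflow that produced them. The worked Red List
  examples validate the categorization logic on the published summary
  numbers instead.
* The minimum-area grid-origin optimization for AOO and line-buffering of
  degenerate hulls (as some range tools do) are documented divergences.
* The rank-test implementation reports exact p-values only up to a
  combined n of 12 by default; beyond that the continuity-corrected
  normal approximation is accurate to about 0.01–0.02 in the far tails.
* Calls are measured assuming a dominant fundamental; species whose
  energy maximum sits on a harmonic would need the harmonic-counting
  fundamental supplied explicitly.
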