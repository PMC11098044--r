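---
title: "Hub disruption analysis of functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub disruption analysis of functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdinet)
```

## The problem and the model

Severe brain injury reorganises the functional connectome rather than
simply weakening it: regions that act as hubs in healthy subjects lose
connectivity while peripheral regions gain it, so global averages of
connectivity or of nodal metrics often show nothing. The hub disruption
index (HDI) is built to see exactly this pattern. Given a nodal metric
(degree, clustering, local efficiency, or betweenness centrality), plot
for every region the individual-minus-reference value against the
reference cohort mean and fit an ordinary least-squares line with
intercept. The slope is the HDI:

* an individual indistinguishable from the reference sits on a
  horizontal line, HDI = 0;
* a disrupted individual — hubs (right of the x-axis) below zero,
  non-hubs (left) above — tilts the line to a negative slope.

The index is invariant to common rescaling of all profiles and to common
shifts (only the intercept moves), so it does not depend on, e.g.,
betweenness normalisation conventions.

## Pipeline stages and their parameters

**Parcel extraction.** Regional series are grey-matter-probability
weighted means of voxel signals, which suppresses white-matter and CSF
contamination. Parcels with zero total probability propagate as missing
columns rather than zeros.

**Quality control.** A volume is an outlier when the composite
inter-volume displacement exceeds 5 mm or the global-signal change
exceeds 3 SD of the global signal. Composite displacement is the
Euclidean norm of the translation change plus the arc displacement of
the rotation change at a 65 mm head radius — the composite convention of
the ART toolbox, since no closed formula is standard in the literature.
Runs with strictly more than 10% outliers are rejected ("more than" read
strictly, so 10/100 keeps and 11/100 rejects). Nuisance regression
projects each region on an intercept, the six motion parameters, and one
indicator per flagged volume; indicators absorb flagged volumes exactly,
the projection is idempotent, and the intercept makes the downstream
correlation estimates offset-invariant.

**Wavelet correlation.** The MODWT (implemented in the package:
pyramid algorithm, periodic boundary, perfect reconstruction and exact
energy conservation) decomposes each series into dyadic bands; level j
covers [1/2^(j+1), 1/2^j] cycles per sample. The analysis band defaults
to 0.032–0.065 Hz, where resting-state covariance concentrates; the
level is chosen by maximal overlap with that band (level 3 at TR = 2 s,
level 4 at TR = 1 s). The filter defaults to Daubechies extremal-phase
d4 (haar and d6 are available). The first L_j − 1 boundary-affected
coefficients of each level are excluded from correlation estimation to
avoid wrap-around bias, and at least 30 usable coefficients are
required.

**Graph construction.** The graph at cost c keeps
floor(c · n(n−1)/2) edges (283 at c = 0.05, n = 107; floor is forced by
that printed pair), never fewer than the n − 1 a spanning tree needs.
"Minimum spanning tree based on the correlation matrix" is read as the
MST under distance 1 − |r| — the maximum-|r| tree — because only that
reading keeps the graph connected through its strongest links; the tree
edges count toward the cost budget. Thresholding then adds the highest
remaining |r| pairs. All orderings use one deterministic tie rule
(|r| descending, then smaller, then larger node index), so outputs are
bit-reproducible and edge sets are nested across costs. Regions with no
usable correlations attach to the tree by their single best available
edge (or one arbitrary edge if none), keeping profiles dense.

**Nodal metrics.** Degree, clustering coefficient
(triangles / k(k−1)/2), local efficiency (mean inverse shortest-path
length in the neighbourhood subgraph), betweenness (fractional counting,
normalised by (n−1)(n−2)/2 by default). The field sometimes conflates
clustering and local efficiency; both are implemented and never silently
mixed — the clustering variant is a configuration choice, default
coefficient. Nodes with fewer than two neighbours score 0 rather than
missing. Modularity (seeded Louvain) is available as an auxiliary global
summary only.

**HDI conventions.** The reference is the node-wise mean of the
individual healthy profiles (not the metrics of an averaged graph; the
alternative reading exists but mixing metric and graph averaging changes
the object being regressed). Healthy subjects are referenced
leave-one-out by default to avoid self-bias in their HDI spread;
patients are never reference members, so the flag cannot affect them.
Plain OLS with intercept is used — no winsorizing or robust variants —
and R², slope SE and the per-node differences are kept for diagnostics.

**Statistics.** Mann–Whitney, Kruskal–Wallis, paired Wilcoxon and
Fisher's exact tests run through the standard R implementations (exact
for small untied samples) behind a uniform result contract; the test
suite checks them against brute-force enumeration oracles. The
longitudinal model is `hdi ~ consciousness * time + (1 | subject)`, REML,
with consciousness coded MCS = 1 / C = 0 and time centred at the first
timepoint, so the intercept is the conscious-group baseline mean. Two
timepoints cannot robustly identify both a random-slope variance and a
residual variance at cohort sizes of a few dozen, so the default random
structure is an intercept only. Confidence intervals and p-values come
from a nonparametric cluster bootstrap (whole subjects resampled with
replacement, percentile intervals, sign-crossing two-sided p). For the
balanced two-timepoint design the fixed-effect estimates of the mixed
model and of OLS coincide (the consciousness covariate is
cluster-constant and time is balanced within every cluster), so the
`bootEngine = "ols"` fast path gives identical resample estimates at a
fraction of the cost; it is used in the large calibration simulations.
Node-wise exploration adjusts per-node rank-test p-values by
Benjamini–Hochberg (default) or Bonferroni.

## The synthetic-cohort generator

The generator emulates the structure of the study data the pipeline is
designed for; clinical recordings are not distributable, so it is the
package's test bed and demonstration input.

* **Template connectome**: 107 regions, 283 edges (5% cost), 10 planted
  hubs grown by preferential attachment with a hub bonus, then repaired
  by degree-preserving edge swaps until the planted hubs strictly hold
  the largest degrees. Empirical connectomes at this cost have heavy
  degree tails; the planted-hub construction makes ground truth
  unambiguous for recovery tests.
* **Covariance**: adjacent regions correlate at `edgeCorr` (default
  0.3) via `I + edgeCorr · A`, shrunk toward the identity until positive
  definite. Shrinkage lowers the realised correlation but preserves the
  adjacent > non-adjacent ordering that graph recovery needs.
* **BOLD series**: white Gaussian noise band-passed to the analysis
  scale and mixed through the Cholesky factor of the covariance —
  400 volumes at TR = 2 s by default, matching long-duration
  resting-state acquisitions. Wavelet correlations at the target scale
  then estimate the planted covariance; a correlation between
  independent regions has roughly n/2^level effective degrees of
  freedom because detail series are band-limited, which is the sampling
  scale all null checks are calibrated against.
* **Disruption**: a `strength` fraction of hub-incident edges is
  removed, the same count (times `rewireFraction`, default 1) is
  re-attached between non-hub pairs, and connectedness is repaired with
  the minimum necessary spanning-tree edges of the original template.
  Strength 0 is the identity; mean hub degree decreases monotonically in
  strength; |HDI| grows monotonically with it. The strength scale is a
  modelling device, not calibrated to clinical severity.
* **Cohorts**: 20 healthy, 9 at strength 0.5 (emulating the minimally
  conscious group), 15 at strength 0.2 (the conscious group) — the
  group sizes of the study structure this package emulates; all
  configurable.
* **Longitudinal tables**: HDI values drawn from the mixed model with
  fixed effects defaulting to (−0.20, −0.24, 0.09, −0.16) — intercept,
  consciousness, time, interaction on the clustering-metric HDI scale —
  and dispersions sd_subject = 0.15, sd_residual = 0.10, chosen once as
  moderate HDI-scale noise of the same order as the spread implied by
  the reported interval widths of such cohorts.

What the generator does **not** emulate: scanner physics and
hemodynamics (the series are Gaussian and exactly band-limited), lesion
geometry, spatially structured artifacts, missing timepoints, and any
voxel-level realism beyond tiny phantoms for extraction tests. Passing
tests therefore demonstrate correctness of the estimators and the
internal consistency of the method under its own assumptions — not
clinical validity on real recordings.

## Numerical choices and degenerate inputs

* All randomness flows through an explicit seed and a restored RNG
  state; nothing touches the caller's `.Random.seed`.
* Tie-breaking is lexicographic everywhere (graphs, hub sets), making
  every artifact byte-reproducible; the end-to-end run writes a manifest
  of md5 checksums to make this auditable.
* Degenerate cases are explicit: a flat reference profile is a
  degenerate-reference error; all-zero paired differences give p = 1
  with a warning; an all-identical Kruskal–Wallis input gives H = 0,
  p = 1 with a warning; a zero-margin Fisher table gives p = 1;
  single-state mixed-model data reduce the model with a warning and NA
  state terms; an all-flagged run is a rank-deficient design error.
* Positive-definiteness is enforced by diagonal loading with a hard
  iteration cap; the BOLD simulator refuses non-PD covariance.

## Problem sizes used in the shipped checks

The package's own test runs use reduced sizes chosen to exercise every
code path at full structural fidelity: the end-to-end pipeline test runs
30 regions x 128 volumes x 10 subjects; power and calibration
simulations use 100–500 replicates at the study's cohort sizes but on
graph-level cohorts (the BOLD layer is exercised separately), and the
bootstrap calibration uses the OLS engine with 199 draws per replicate.
The statements they verify (recovery within ±0.05 at n = 200 subjects,
type-I error within [2%, 9%], rejection power ≥ 80%) are properties of
the full-scale configuration as well.

## Known limitations

* The MODWT uses periodic boundary handling; reflection is not
  implemented (boundary coefficients are excluded from estimation
  instead).
* The disruption model operates on binary edges, not on correlation
  magnitudes; it realises the hub/non-hub reversal the HDI summarises
  but is not a biophysical lesion model.
* With two timepoints the random-slope variance is intentionally not
  estimated by default.
* Exact rank tests fall back to normal approximations in the presence
  of ties, as do the reference implementations they delegate to.
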