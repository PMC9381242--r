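---
title: "Methods: network topology features and whale-optimized kernel regression"
author: "netcog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network topology features and whale-optimized kernel regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open — in the same
spirit in which variance-modelling packages document their shrinkage
estimators. Everything stated here is either a definition or a property the
test suite computes; no empirical claim is made beyond what the tests and
the acceptance script verify.

## 1. From time series to binary networks

A subject is an ROI×timepoint matrix (default 90 regions × 230 volumes).
`correlation_matrix()` forms the Pearson correlation between every pair of
regional time series; `fisher_z()` applies z = ½·ln((1+p)/(1−p))
elementwise off the diagonal. The diagonal of the Z-matrix is stored as 1
purely as a notational convention — Fisher-Z of a unit correlation is
infinite, and no downstream computation reads the diagonal.

`binarize_at_sparsity()` keeps the m = round(s·n(n−1)/2) strongest edges at
sparsity s. Two conventions had to be fixed where common practice varies:

* **Edge ranking** uses the signed weight (most positive first), the
  dominant convention for binarized functional connectomes; magnitude
  ranking is available via `ranking = "absolute"`.
* **Ties** are broken by lexicographic (row, column) order, which makes
  binarization deterministic and gives the nesting property that the edge
  set at sparsity s is a subset of the edge set at any s′ > s.

Perfect off-diagonal correlations (possible in synthetic data) are clipped
to ±(1 − 10⁻⁷) with a warning before the transform.

The sparsity grid is the 31 values 0.10, 0.11, …, 0.40, realized by integer
stepping so no threshold drifts in floating point.

## 2. Topological metrics and their AUCs

Seven global metrics are evaluated at every grid point
(`metric_curves()`): global efficiency, local efficiency, mean clustering
coefficient, characteristic path length, and the normalized γ, λ, σ. Fixed
conventions, stated so the tests can be exact:

* Nodes with degree < 2 contribute 0 to the clustering coefficient and to
  local efficiency.
* Local efficiency of a node is the global efficiency of the subgraph
  *induced by its neighbours* — paths may not detour through the rest of
  the graph. (This is why the computation is done in-package rather than
  with `igraph::local_efficiency()`, which implements the
  paths-through-anywhere variant.)
* Characteristic path length averages over *reachable* ordered pairs only,
  with a warning when the graph is disconnected; a graph with no connected
  pair is an error. Efficiency-based metrics handle disconnection natively
  through 1/∞ = 0.
* γ = Cp/⟨Cp_null⟩ and λ = Lp/⟨Lp_null⟩ use Maslov–Sneppen
  degree-preserving double-edge swap null models (`rewire_null()`), the
  field standard, with 10 swap attempts per edge and a fresh ensemble per
  sparsity (100 graphs by default; the tests use 20 to keep the suite
  fast). Whether the original analysis used per-sparsity ensembles or one
  shared ensemble is not documented anywhere we could find; per-sparsity
  ensembles are assumed.
* The AUC of each metric curve is the composite trapezoid rule on the
  exact grid — exact for linear curves, which anchors the unit tests.

All distance-based metrics are verified against a brute-force
Floyd–Warshall oracle, and local efficiency against per-node induced
subgraph enumeration, to 10⁻¹² on hundreds of random graphs of up to 8
nodes.

## 3. PCA feature weighting

The seven AUC features (canonical order γ, λ, σ, Cp, Lp, Eglobal, Elocal)
are standardized to unit sample SD, their correlation matrix is
eigendecomposed, and each eigenvalue's share of the total variance becomes
a feature weight; features with weight > 0.6 are selected.

One step here is mathematically under-determined: eigenvalues belong to
eigenvectors, not to original features, so "the weight of feature j" needs
an attribution rule. The default pairs each eigenvector, in descending
eigenvalue order, with the not-yet-claimed feature carrying its largest
absolute loading (ties by lowest index) — a one-to-one greedy matching that
preserves Σw = 1 and is permutation-equivariant. The literal order-pairing
(j-th eigenvalue ↔ j-th feature) is available via `attribution = "order"`.
Because weights sum to one, a 0.6 threshold admits at most one feature;
when nothing clears it the largest-weight feature is selected with a
warning. Eigenvector signs are fixed so the largest-magnitude component is
positive, making projections (`project_component()`) deterministic.

PCA selection is fitted on the patient group of the training fold only
(the group whose scores are being predicted); pooled fitting is a
one-argument change. The default pipeline predictor is the selected *raw*
AUC feature (in practice Elocal AUC); the principal-component projection is
provided but not used by default.

## 4. LSSVR

The least-squares SVR primal (squared slacks, equality constraints)
reduces through its KKT conditions to the (n+1)×(n+1) saddle system shown
in the README; the feature map is never materialized. The dual solution
satisfies Σaᵢ = 0 identically, and the solver asserts the system residual
is below 10⁻⁸. The RBF kernel is exp(−‖x−x'‖²/σ²) — note the width enters
without a factor 2, so σ² here equals 2σ²_textbook.

Inputs are standardized with training-fold mean/SD before kernel
evaluation; a width parameter is meaningless on unscaled features.
Defaults J = 100, σ² = 1 (on standardized inputs): σ² = 1 is the canonical
unit-bandwidth choice and J = 100 a mild ridge. Exact leave-one-out
residuals are available in closed form from a single solve
(`lssvr_loo_residuals()`, residual aᵢ/(M⁻¹)ᵢᵢ), verified against literal
refitting.

## 5. WOA and the Lévy-flight variant

Each of (default) 20 whales updates by one of three moves: encircling the
best-so-far position (|H| < 1, p < 0.5), a random-search move toward a
random whale (|H| ≥ 1, p < 0.5), or a logarithmic spiral around the best
(p ≥ 0.5), with H = 2h·r − h, C = 2r₂, and the distance terms taken in
absolute value as in classic WOA. The best-so-far is updated immediately
whenever any whale improves on it; positions are clipped to the box.

The standard variant draws r uniformly and uses the linear schedule
h = 2 − 2t/T, under which |H| ≤ h ≤ 1 for t ≥ T/2 — past the midpoint the
random-search branch can no longer fire. The Lévy variant replaces r by a
Mantegna-sampled stable step s = μ/|ν|^(1/β) (β = 1.5,
σ_μ = 0.6966 ≈ 0.7 from the closed form) so that long jumps remain
possible at any iteration, and swaps the schedule for one that decays
slowly early and exponentially late. The published closed form of that
schedule is typographically ambiguous in every source we have; the default
implementation h(t) = 2·exp(0.15 − (t/T)⁴·ln 10) satisfies the stated
behavioural contract (h(1) ≈ 2e^0.15 ≈ 2.32, monotone, slow-then-fast
decay), the alternatives are registered in `h_schedules()`, and only the
behavioural contract is asserted by tests.

## 6. Hyperparameter tuning inside cross-validation

(J, σ²) are searched in log₁₀ space over J ∈ [10⁻², 10⁴],
σ² ∈ [10⁻³, 10³] (population 20, 100 iterations by default; the test suite
uses 10×20, stated sizes, to keep the default run fast). Three design
choices matter and were made after observing concrete failure modes on
synthetic cohorts:

* **Fitness = exact leave-one-out RMSE of the training fold**, not
  subsampled inner k-fold (which remains available via
  `tuner_control$objective = "kfold"`). Near-interpolating candidates
  (large J, mid σ²) can be docile at the inner-fold size yet wild at the
  full fold size; LOO evaluates every candidate at deployment size for the
  cost of one linear solve.
* **Extrapolation probes.** No leave-out estimate can certify behaviour
  outside the training hull, yet held-out folds routinely contain the
  sample extremes. Candidates are therefore rejected when their
  predictions at probe points 0.5–1.5 feature-SDs beyond the observed
  range leave a mean ± 4 SD plausibility band of the training scores.
  Predictions are additionally clipped to the 0–30 clinical scale
  everywhere, mirroring the scale's definition.
* **One-standard-error adoption gate.** The tuned candidate replaces the
  untuned defaults only when its fitness improves on theirs by more than
  the delta-method standard error of the fitness estimate (the same
  parsimony idea as `lambda.1se` in penalized regression). With ~45
  training subjects the fitness SE is ≈ 0.1–0.2 score points; when the
  true tuning headroom is smaller than that, the winner's-curse cost of
  always adopting the argmin exceeds the benefit, and the gate makes
  tuning a strict no-regret operation. On cohorts with real headroom
  (e.g. noiseless score links) the gate adopts in every fold.

## 7. Cross-validation protocol and error metrics

Prediction uses the patient group only; controls enter the group-level
statistics. `stratified_kfold()` stratifies a continuous target by
score-quantile bins (5 by default — the spec of "stratified sampling"
names no variable), shuffles within bins and deals cyclically, so fold
sizes differ by at most one (50 subjects / 10 folds → exactly 5 each). The
same partition (per seed) is shared by all four variants, so comparisons
are paired. Graph features are extracted once before cross-validation —
legitimate because no labels are used — while selection and tuning are
refitted inside every training fold. RMSE, MAE and MAPE (as a fraction)
are computed per fold and averaged arithmetically.

The region-level analysis correlates each region's node efficiency with
the score (r, p per region, uncorrected p < 0.05 to match common practice
in this literature, with an optional Benjamini–Hochberg switch); a joint
multiple-regression mode is available behind `method = "multiple"` since
per-region correlations are what such studies actually report.

## 8. The synthetic cohort generator

No public data accompanies this problem, so the generator defines the
study conditions. ROIs are partitioned into consecutive modules of 10; ROI
i carries x(t) = L·f_m(t) + ε(t) with a shared standard-normal module
signal f_m, unit-variance noise, and loading L = 0.7 for controls reduced
by 0.2 for patients. This is the simplest model with tunable group
differences in local-efficiency AUC; patients' weaker within-module
correlation makes their binarized networks less locally clustered, so
their Elocal AUC is lower — the direction reported for patient cohorts.
Default sizes are 50 patients / 40 controls, 90 ROIs, and 230 timepoints
(a typical 240-volume acquisition minus 10 discarded start-up volumes; the
run length is an assumption, flagged here, not a protocol fact).

Scores follow score = −61 + 400·ElocalAUC + N(0, 1.5²), clipped to
[0, 30]. The slope and intercept were calibrated once against the
generator so that group mean scores land near 21.5 (patients) and 27.4
(controls) — the score profile typical of such cohorts — and the noise SD
of 1.5 sits between the two groups' reported score SDs. The generator is
seeded with one master seed, split per subject by counter, so cohorts are
byte-for-byte reproducible and subject generation is order-independent.

What the generator does *not* emulate: haemodynamic dynamics, spatial
structure, motion or physiological confounds, site effects, and any
nonlinearity in the score link. Passing tests therefore demonstrate that
the pipeline recovers the signal it was built to exploit under its own
stated assumptions — not that it would perform identically on clinical
fMRI.

## 9. Degenerate inputs and numerical tolerances

Zero-variance ROI rows are an error naming the row; constant feature
columns are an error naming the feature; |p| = 1 clips with a warning;
singular KKT systems raise an error with a conditioning diagnostic;
non-finite optimizer objectives trigger bounded resampling before
erroring. Dual-constraint residuals are asserted below 10⁻⁸, oracle
agreements at 10⁻¹² (graph metrics) and 10⁻⁸ (LSSVR vs independent dense
solve), and the trapezoid/eigen identities at 10⁻¹⁰–10⁻¹².

## 10. Known limitations

* γ/λ/σ require null ensembles at every sparsity; at the default 100
  nulls per grid point this is by far the most expensive stage, and
  analyses that only need Elocal should request only it.
* The score link being linear in a single feature means kernel-width
  tuning has little to do on default synthetic cohorts; the adoption gate
  makes this safe but also means tuned and untuned variants often
  coincide there.
* MAPE is undefined when a true score is 0; with the default score link
  this does not occur, but arbitrary feature tables must guard it.
* The ε-SVR comparator is delegated to a stock implementation with fixed
  (cost = 1, ε = 0.1) defaults; it is a baseline, not a tuned rival.
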