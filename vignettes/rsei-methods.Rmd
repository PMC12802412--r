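---
title: "Methods behind rseikit: indicator fusion, temporal dynamics and driver detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind rseikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rseikit)
```

# The problem

Arid and semi-arid steppes degrade through the joint action of vegetation
loss, soil drying, bareness expansion, heat stress and salinization. A
single composite index built from multispectral reflectance lets these
stressors be monitored together on every pixel of a long satellite record.
`rseikit` implements such an index for MODIS-style band stacks (red b1, NIR
b2, green b4, SWIR1 b6, SWIR2 b7, plus an LST DN grid), along with the
downstream change, stability, persistence and driver analyses, and a
ground-truthed scene simulator that makes the whole chain verifiable at
desk scale.

# Component indicators

Water is masked before anything else: open water has extreme humidity and
dryness spectra that would dominate the principal-component fusion, so
pixels with MNDWI = (b4 − b6)/(b4 + b6) above a threshold (default 0,
configurable) are excluded from all statistics. Only non-water ecological
quality is assessed.

The five indicators per land pixel:

* **Greenness, SAVI** = (1 + L)(b2 − b1)/(b1 + b2 + L). The soil-adjustment
  constant L (default 0.5, the standard empirical value) damps the bright
  bare-soil background that inflates NDVI in sparse vegetation; L = 0
  recovers NDVI exactly.
* **Humidity, SWCI** = (b6 − b7)/(b6 + b7), driven by liquid-water
  absorption in the shortwave infrared; more sensitive than tasseled-cap
  wetness under low canopy cover.
* **Dryness, NDBBI** = (1.5 b6 − (b2 + b4)/2)/(1.5 b6 + (b2 + b4)/2).
  The grouping of the NIR + green term is ambiguous in some typeset
  sources; we follow the original index definition (the half-sum in both
  numerator and denominator) and expose the alternative literal grouping
  via `computeNdbbi(..., grouping = "whole")`.
* **Heat, LST** = 0.02 DN − 273.15, the linear DN-to-Celsius conversion for
  MODIS-style LST products (scale and offset configurable).
* **Salinity, CSI**: three salinity indices — SI-T = 100 b1/b2,
  NDSI = (b1 − b2)/(b1 + b2), SI4 = b6/b2 — are each min–max normalized to
  [0, 1] over the land cells of the epoch and averaged. A multi-index mean
  is more robust across heterogeneous surfaces than any single salinity
  index, and CSI lies in [0, 1] by construction.

Reflectance values outside [−0.01, 1.6] are treated as nodata before any
band math; this window tolerates slight atmospheric-correction overshoot
while rejecting fill values and sensor artifacts. Any arithmetic with a
masked operand yields a masked cell.

# Index fusion

Each indicator layer is normalized to [0, 1] by its per-image min and max
over land cells, removing the dimensional mismatch between, e.g., °C and
unitless ratios. The index is the first principal component of the
**covariance** matrix of the five normalized layers — not the correlation
matrix — because after common [0, 1] scaling the residual variance
differences are informative; this is also the convention under which
published loading tables for this family of indices are reproducible. A
correlation-matrix variant is available via `fitPca(x, useCorrelation =
TRUE)`.

Eigenvector sign is arbitrary in any solver, so published workflows apply a
"1 − PC1" flip "as needed". We replace that per-case judgement with a
deterministic rule: if the PC1 scores correlate negatively with SAVI over
land, they are negated. After min–max rescaling to [0, 1] this is exactly
equivalent to the conditional 1 − PC1 transformation and guarantees the
index increases with greenness in every epoch. The flip is recorded in the
`oriented` flag of the `PcaResult`.

Grades use fixed, lower-inclusive thresholds — bad [0, 0.2), poor
[0.2, 0.4), moderate [0.4, 0.6), good [0.6, 0.8), excellent [0.8, 1] —
with the top bound closed so an index of exactly 1 is gradable. Each epoch
is fitted independently (its own water mask, normalization and PCA), as in
per-year published loading tables. Area accounting assumes equal-area cells
on a projected grid: area = cell count × cell_size².

# Temporal dynamics

**Change grading.** Change vector analysis operates on the ordinal class
codes, not on raw index differences: Δ = class(t2) − class(t1) ∈ [−4, 4],
binned as deteriorated significantly [−4, −2], deteriorated {−1}, unchanged
{0}, improved {1}, improved significantly [2, 4]. FROM–TO transitions are
cross-tabulated with km² and percent-of-land columns, diagonal included;
marginals reproduce the per-epoch class histograms by construction.

**Stability.** The per-cell coefficient of variation across epochs defaults
to population standard deviation over mean — the universal CV definition —
with the mean-absolute-deviation variant (`estimator = "mad"`) preserved as
an option because some typeset sources print the formula in that form.
Levels use the fixed breakpoints 0.10/0.20/0.30/0.40; CV above 1 stays in
level 5. Cells with nonpositive mean are masked rather than given a signed
CV.

**Persistence.** The Hurst exponent is estimated by classical rescaled
range: for each window length τ from 2 to ⌊n/2⌋ the series is cut into
⌊n/τ⌋ non-overlapping segments; each segment contributes
R/S = range(cumulative mean-adjusted sums)/population sd, zero-variance
segments are skipped; H is the least-squares slope of log(mean R/S) against
log τ, requiring at least 3 valid points, clipped to (0, 1] because
estimates outside that range at n ≈ 12 are finite-sample artifacts. The
window protocol is the textbook small-n choice (for n = 12 epochs it scans
τ ∈ {2, …, 6}); no overlapping-window or bias-corrected variant is applied,
so on white noise the estimator sits slightly above 0.5, a documented
property of classical R/S at finite n. Persistence classes: strong
antisustainability [0, 0.35), weak antisustainability [0.35, 0.50), weak
sustainability [0.50, 0.65), strong sustainability [0.65, 1]. Cells whose
series is constant (typically the per-image min/max anchor cells of an
otherwise noise-free simulation) cannot be estimated and are masked.

# Driver detection

The q-statistic of a stratification h of sample set N is computed in its
sum-of-squares form q = 1 − SSW/SST, algebraically identical to the
1 − Σ N_h σ_h²/(N σ²) weighted-variance form when variances are population
variances (denominator N_h); the package uses population variances
throughout precisely so the two forms agree to machine precision and q is
exactly partition-additive. Listwise deletion is applied per (response,
factor) pair; no imputation.

Continuous drivers are discretized by five methods:

* *equal interval*: breaks at min + i(max − min)/k;
* *natural breaks*: exact Fisher–Jenks dynamic programming (O(kn²), in
  C++) minimizing SSW over contiguous value-ordered classes; above
  n = 10 000 the DP runs on 10 000 evenly spaced order statistics of the
  sorted sample — a deterministic reduction that needs no RNG state; cut
  points are midpoints between adjacent-class neighbours;
* *quantile*: type-7 empirical quantiles at i/k, duplicates merged;
* *geometric*: breaks b_i = min + (max − min)(gⁱ − 1)/(g^k − 1), g = 2 by
  default — a deterministic geometric-progression parameterization,
  monotone in class index (the method is usually named but not specified
  in the applied literature);
* *standard deviation*: breaks at mean + f·s·(i − k/2) with step f = 0.5,
  clamped to the data range — likewise a documented parameterization of a
  method that sources name without defining.

Labels use half-open bins [b_{i−1}, b_i) with the top bin closed. The
optimal-parameter search scans every (method, k) pair for k in 5–10 (both
configurable) and keeps the q-maximizing pair; ties break toward smaller k,
then method order as listed above, making the selection reproducible.

Significance is a seeded permutation test — p = (1 + #{q_perm ≥ q_obs}) /
(1 + n_perm) with the response permuted and strata fixed — rather than the
noncentral-F approximation sometimes used, because the permutation test is
assumption-free and exactly reproducible under the run seed.

Interactions overlay two stratifications as their cartesian product (empty
cells drop out). Since the product refines both marginals, q_ij ≥
max(q_i, q_j) up to rounding; categories follow the standard scheme
(nonlinear weaken / single-factor weaken / bi-factor enhance / independent
/ nonlinear enhance), with q_ij equal to the larger marginal classified as
bi-factor enhance and equality with q_i + q_j (±1e−9) as independent.

Sampling uses every k-th cell in both axes (`sampleGrid`), the regular
grid-unit scheme of driver-analysis practice; masked response cells are
dropped.

# The synthetic scene generator

The simulator is the package's test surface, not an afterthought. Its
latent quality field E is white Gaussian noise smoothed separably with a
Gaussian kernel at a stated correlation length (default 8 cells — broad
enough to give each grade contiguous regions on a 64–128 px scene) and
min–max scaled to [0, 1]. Bands respond linearly to E with signs mirroring
the loading structure expected of the real indicators: b2 (NIR) rises with
E; b1, b4, b6, b7 fall; LST encodes 18 + 20(1 − E) °C in DN units. Noise
(default sd 0.01 reflectance) is added per band and values are clipped to
[0.01, 0.95]. Water bodies are contiguous blobs (union of disks around
seed centres, one centre per ~400 target water cells, with the distance
threshold set to the requested area quantile so the realized fraction is
exact) whose b4/b6 overrides make them MNDWI-positive. Time series shift E
by t·trend per epoch, clipped to [0, 1]; a trend of −0.03 over 12 epochs
(the default degradation experiment) moves the median cell down one grade
or more. Drivers are built by stratifying E into k quantile bins and
generating a validation response y = μ_d + ε with noise variance
σ² = Var_between·(1 − q₀)/q₀, so the population q of y given the strata
equals the requested q₀.

What the simulator does **not** emulate: sensor point-spread functions,
atmospheric residuals, cloud gaps, phenology, spatially correlated noise,
or any nonlinearity between stressors and reflectance. Passing tests
therefore demonstrate algorithmic correctness and calibration of the
implementation — not validation of the index against field truth, which
requires real archives and external reference data.

All randomness flows through R's default Mersenne-Twister generator under
the spec seed; identical specs produce bit-identical scenes, and the
per-epoch band noise uses seeds derived arithmetically from the spec seed.

# Numerical choices and degenerate inputs

* Min–max normalization requires max > min; constant layers raise an error
  naming the layer rather than returning NaN.
* Division guards: zero denominators in any ratio index mask the cell;
  SAVI additionally masks nonpositive denominators.
* Index classification tolerates 1e−12 of numerical overshoot outside
  [0, 1] and errors beyond that.
* q-statistic: single-sample strata contribute zero to SSW; SST = 0 is an
  error (degenerate response).
* Fisher–Jenks comparisons use a 1e−15 guard so equal-cost splits resolve
  to the leftmost boundary deterministically.
* Grids must be pre-aligned; `alignCheck` compares shape, origin, cell
  size and CRS tag exactly, and every multi-grid operation asserts
  alignment. The toolkit never resamples or reprojects — upstream GIS
  tooling owns that step, keeping the numerics here deterministic.
* Rasters are stored in the ESRI ASCII grid text format with a `.prj`
  sidecar; values are written with 17 significant digits so round-trips
  are bit-exact.

# Problem sizes

The test-suite and acceptance experiments run at desk scale, chosen to keep
every property measurable with comfortable margins: 12-epoch series on
128×128 grids for the end-to-end run, 100×100 (n = 10 000) for driver-q
recovery, n = 1024 for the white-noise Hurst calibration, and exhaustive
enumeration oracles at n ≤ 12 for the Fisher–Jenks check. Published
headline values from continental-scale archives (e.g., multi-year mean PC1
contributions above 90%) are not reproduction targets at this scale,
though the synthetic runs land in the same regime.

# Known limitations

* The index is relative per epoch (per-image normalization and PCA), so
  absolute values are not comparable across regions processed separately.
* Classical R/S is biased upward at small n; no Anis–Lloyd correction is
  applied.
* The water mask is binary and epoch-independent in the simulator;
  seasonal water-extent dynamics are not modelled.
* The geometric and standard-deviation discretizers are documented
  parameterizations of methods whose applied usage varies; results for
  those two methods should be read with that in mind.
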