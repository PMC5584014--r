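---
title: "Dual-optimized NIRS calibration: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-optimized NIRS calibration: models, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duopls)
```

`duopls` builds near-infrared (NIRS) calibration models for the stem
composition and theoretical ethanol yield of bioenergy sorghum, optimizing
both the calibration/validation sample split and the wavelength subset. This
vignette is the package's own account of the science: the models it
implements, what every tunable default means and why it has the value it
has, what the synthetic data generator does and does not emulate, and where
the method's known limitations are.

## The measurement model

A dried, milled stem sample is scanned in diffuse reflectance from 4000 to
10000 cm^-1; the instrument class this emulates records 1557 absorbance
variables at ~3.86 cm^-1 spacing. Absorbance in this range is driven by
C–H/O–H overtone and combination bands of the organic constituents, so a
sample's spectrum is, to first order, a linear mixture of component spectra
weighted by mass fractions (Beer–Lambert), distorted by

* a multiplicative scatter factor (particle-size and packing effects),
* an additive baseline, roughly linear in wavenumber (drift, offset),
* additive instrumental noise.

The preprocessing chain undoes these in order:

1. **MSC** (multiplicative scatter correction): each spectrum is regressed on
   the mean spectrum, `x = a + b·m`, and replaced by `(x − a)/b`. This
   inverts per-spectrum affine scatter exactly when the reference is fixed;
   with the default mean-spectrum reference the correction is the standard
   approximation.
2. **Norris smoothing**: a moving average over `norris_segment = 5` points.
   Edge points use truncated windows, which preserves the axis length but
   distorts a linear ramp at the outermost two points of each edge — a known
   and documented edge effect.
3. **Gap first derivative**: `d_i = (x[i+g] − x[i−g]) / (ν[i+g] − ν[i−g])`
   with `derivative_gap = 5`. Constants are annihilated exactly; a linear
   baseline becomes a flat offset (its slope), which the subsequent
   mean-centering of PLS removes. The output axis is truncated by `g` points
   per side rather than padded, so every emitted value is exact; all
   downstream variable indices refer to the truncated axis (1547 variables
   from 1557).

The segment and gap values are conventional mid-range settings for this
filter family; the method this package follows names the filter but not its
parameters, so these are declared package defaults, not reproduced settings.

## Sample-subset partitioning

`make_partition()` supports random splits, Kennard–Stone (max–min selection
on spectral Euclidean distances), and SPXY, which normalizes spectral and
property distances by their maxima and sums them, so both spaces contribute
equally to the inter-sample distance. With the default
`validation_fraction = 0.25`, one of every four samples is held out (147
samples split 110/37).

Design choices a user should know:

* The selection algorithm picks the **calibration** set; the complement is
  validation. Extremes are swept into calibration, so validation rarely
  requires extrapolation. This is a tendency, not a theorem — on small
  simulated populations a y-extreme sample inside a dense spectral cluster
  occasionally stays out of calibration (~6% of draws in our property
  tests, versus ~48% for random splits).
* Distances are computed on whatever matrix is handed in; the pipeline hands
  in preprocessed spectra, matching the modeling matrix.
* Ties break toward the lowest sample index, making selections fully
  deterministic and permutation-equivariant up to ties.

## PLS1 calibration and evaluation

`fit_pls()` implements NIPALS PLS1 with mean centering, one property at a
time, storing the coefficient path for all factor counts up to `n_factors`.
At full rank it reproduces ordinary least squares to 1e-8, which the test
suite uses as an algebraic oracle.

* **Factor selection**: leave-one-out cross-validation (`loo_cv()`) produces
  an RMSECV profile; `select_factors()` picks the *smallest* factor count
  within 2% of the minimum RMSECV. The parsimony tolerance is a package
  choice: the emulated study reports 5–9 factors but not its selection rule.
  The cap is `max_factors = 15`.
* **Outlier removal**: up to two rounds drop samples with score leverage
  above `3 · (k+1)/n` or absolute studentized y-residual above 2.5, then
  refit. The thresholds reproduce a 110 → 108 calibration count on
  planted-outlier synthetics; removing more than 10% of samples sets a
  warning flag instead of being trusted silently.
* **Metrics**: RMSEC/RMSECV/RMSEP in property units; R² values are squared
  Pearson correlations between predicted and reference values (not
  1 − SSE/SST; the two differ under prediction bias, and the
  correlation-based reading matches how validation scatter plots are
  conventionally summarized); RPD = sd(y_val)/RMSEP; RER = range/RMSEP with
  the range taken over the **full** sample set's reference values. The
  full-set reading is adopted because it is the one consistent with the
  quantity this package cross-checks in its acceptance tests
  ((47.6 − 5.4)/2.57 = 16.42); a validation-only reading is available by
  passing `y_range` explicitly.

## Wavelength selection

Five algorithms, all operating on the outlier-cleaned calibration subset:

* **CARS** — `n_runs = 50` Monte Carlo runs; each fits PLS on a random 80%
  of samples over the currently retained variables and resamples variables
  (weighted by |coefficient|, without replacement) down to the count given by
  an exponentially decreasing schedule fixed by "all variables at run 1, two
  at the last run". Each run's subset is scored by 5-fold cross-validation
  (a deliberate speed choice — final model assessment always uses
  leave-one-out), and the best-scoring subset wins.
* **SR** — the ratio of explained to residual variance of each variable
  under target projection onto the normalized regression vector; threshold
  is the F critical value at α = 0.05 with (n−2, n−3) degrees of freedom.
* **VIP** — the usual weighted norm of PLS weights scaled by per-factor
  explained response variance, cutoff 1.0; mean squared VIP is exactly 1 by
  construction, an identity the tests verify.
* **UVE** — appends one artificial noise variable per real variable
  (uniform draws scaled by 1e-10 of the data scale, so they cannot affect
  the fit numerically but yield a stability null), computes coefficient
  stability mean/sd over all leave-one-out submodels, and keeps real
  variables whose |stability| exceeds the maximum |noise stability| — the
  strictest published cutoff convention.
* **MC-UVE** — as UVE with stability over `n_models = 500` random 80%
  subsample refits.

`categorize_consensus()` counts, per wavelength, how many methods selected
it, and classes variables as most-important (5) down to uninformative (0),
with per-class counts and percentages of the 1547 usable variables.

### A known limitation of the strict UVE cutoff

On this package's synthetic populations, a 110-sample calibration model is
very stable, so the maximum over ~1550 noise-variable stabilities is a high
order statistic, and UVE/MC-UVE retain only a few dozen variables. That is
enough for single-band properties (soluble sugar) but underfits properties
whose signal is spread across many bands (ash, TEY, hemicellulose), where
the UVE/MC-UVE dual models trail the full-spectrum control by up to ~0.15
R²V, and it means UVE does *not* retain the largest variable subset here,
as it does in several published comparisons on real instrument data. The
behavior follows directly from the max-cutoff convention; users who want
UVE to behave less conservatively can lower `cutoff_quantile`. CARS and VIP
track the full-spectrum control within ~0.03 R²V while using 5–25% of the
variables, which is the qualitative dual-optimization finding this package
reproduces.

## Qualitative classification

`rate_curve()` fits centered PCA (SVD) and a Mahalanobis-distance linear
discriminant (pooled within-class covariance — classic LDA, matching the
"linear" in the method's name; a singular covariance is ridge-regularized by
1e-8 and flagged) for every component count up to 40, reporting the
resubstitution correct-classification rate and cumulative explained
variance. Resubstitution is the default because it matches how such curves
are conventionally produced by instrument software; a leave-one-out variant
(`loo = TRUE`) is provided for honest error estimation. On default synthetic
populations the two classes separate at 99.3–100% by 20 components.

## Theoretical ethanol yield

The TEY equations convert percent-dry-weight composition to g ethanol per kg
dry matter through the constants 1.11 (sugar from structural
polysaccharide), 0.51 (ethanol from sugar), 0.85 (process efficiency) and
0.79 g/mL (ethanol specific gravity). Percent inputs are divided by 100
before the ×1000/0.79 scale: that is the only dimensional reading under
which the printed constants give yields on the observed few-hundred-g/kg
scale, and it is validated by the package's plausibility tests (generated
populations span ~270–460 g/kg, overlapping the observed 287–429 g/kg).

## The synthetic data generator

There is no public dataset for the emulated study, so `synthetic_dataset()`
is a first-class, tested module that generates populations with the
statistical structure the analyses assume:

* **Composition** (`generate_composition()`): class-wise truncated
  multivariate normals over (sugar, cellulose, hemicellulose, lignin, ash),
  with printed class ranges honored exactly by rejection sampling (capped at
  10^4 rejections, then an error). Class means are calibrated to the printed
  class-wise yield means (sweet hexose TEY ≈ 255 g/kg, biomass pentose TEY
  ≈ 112 g/kg, similar class totals ≈ 341 g/kg) and to the observed
  class-separability (99.3% at 20 PCs). The shared correlation matrix
  encodes hemicellulose's positive association with lignin and ash and its
  negative association with the soluble and insoluble carbohydrates, which
  forces the observed correlation signs with TEY (sugar +, hemicellulose −,
  lignin −, ash −). Means and dispersions are declared package defaults;
  the source population's full descriptive statistics are not public.
* **Spectra** (`generate_spectra()`): Gaussian bands at the midpoints of the
  literature band-assignment regions for each component (e.g. cellulose at
  4018.5, 4402, 4770, 5786, 6332.5, 6798.5, 7316.5 cm^-1; the water O–H
  band at 5172.5 cm^-1), σ = 45 cm^-1, linear Beer–Lambert mixing of mass
  fractions, a constant 4% residual-moisture water fraction, then the
  distortions of `noise_model()`: lognormal multiplicative scatter
  (sd 0.05), linear baseline (offset and slope sds 0.01), additive white
  noise (sd 0.002 AU). Under these defaults the six full-spectrum models
  land at R²V ≈ 0.83–0.99, the intended "good screening calibration" regime.
* **Ash**: physically, ash has no NIR bands and is inferred from its
  association with the organic matrix. A generator that followed that
  strictly would make ash unidentifiable from zero-noise spectra and
  untestable end to end, so the library gives ash two moderate broad
  "mineral-matrix" features (4600 and 5500 cm^-1, widths 60/70 cm^-1) sized
  so ash is about as recoverable as the organics. This is explicitly a
  synthetic identifiability device; conclusions about real-world ash
  calibration should not be drawn from the synthetic ash results.

What the generator does **not** emulate: Kubelka–Munk diffuse-reflectance
physics, overtone/combination band shapes beyond Gaussians, instrument line
shape and the exact (unpublished) wavenumber grid, wavelength-correlated
noise, and any real covariance between class and spectral artefacts.
Passing tests on this generator therefore demonstrate the correctness and
internal consistency of the algorithms under a realistic linear-mixture
population — not instrument-level performance on real sorghum.

## Determinism and numerical choices

* Every stochastic routine takes a `seed` and restores the caller's RNG
  state; the pipeline derives independent per-stage substreams from the
  master seed, so whole-report JSON output is byte-identical across reruns.
* Kennard–Stone ties break to the lowest index; CARS weights get a 1e-12
  floor to keep zero-coefficient variables drawable; SR flags zero-residual
  variables as infinite and selects them; a singular pooled covariance in
  LDA is ridge-regularized (1e-8 of the mean diagonal) and flagged; PLS
  stops extracting factors when the residual covariance norm falls below
  1e-12 (exact-fit regime) and degenerate selections (< 2 variables) fall
  back to the two top-scoring variables so a comparison record always
  exists.
* Problem sizes used by the test suite: full-scale runs use the default
  147 × 1557 population; algorithm property tests use compact instances
  (e.g. 110 × 200 planted-signal regressions, 64-sample populations on a
  400-point axis) chosen to exercise the same code paths at interactive
  speeds.

## Pipeline contracts

`run_quantitative()` shares one SPXY partition and one outlier-cleaned
calibration set across the six strategies of each property, so strategy
comparisons are paired; outlier removal precedes variable selection so every
strategy sees identical samples. `run_qualitative()` reports the full rate
curve, the best component count, and per-sample distances and assignments.
Spectra/reference alignment is enforced by sample id everywhere — silent
misalignment being the classic chemometrics failure mode — and CSV is the
single spectra interchange format (wide matrix, wavenumber header,
descending axis), an artifact convention chosen for bit-exact round trips.
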