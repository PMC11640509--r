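---
title: "Assessing 'Starkrimson' pear maturity from NIR spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing 'Starkrimson' pear maturity from NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

'Starkrimson' pears are harvested over a few weeks in midsummer; picking too
early or too late costs storability and eating quality. Classical maturity
indices combine destructive measurements — soluble solids content (SSC,
°Brix), titratable acidity (TA), CIELAB peel color (L\*, a\*, b\*, C\*, h°),
peel hardness (Fp) and flesh firmness (Ff, both N), and the iodine starch
pattern index (SPI) — into a single number per fruit. Near-infrared (NIR)
absorbance spectra (4000–12,500 cm⁻¹) respond to the same underlying
chemistry (water, sugars, cell-wall polymers), so a calibrated spectral model
can estimate maturity non-destructively.

`nirpear` implements the full workflow: four maturity indices, five spectral
pretreatments, CARS wavelength selection, PLS regression with Kennard–Stone
partitioning, and a three-class maturity labeling with five classifiers. A
seeded synthetic-orchard generator supplies spectra, quality tables and
post-ripening tables with the statistical structure the analysis assumes, so
every stage is testable without instrument data.

## Maturity indices

For each fruit, with F = flesh firmness Ff:

* Streif index: $F / (\mathrm{SSC} \times \mathrm{SPI})$,
* ripening index: $\mathrm{RPI} = \ln(100 \, F \, \mathrm{TA} / \mathrm{SSC})$,
* internal quality index:
  $\mathrm{IQI} = \ln(100 \, F \, \mathrm{TA} \, L^* h° / (\mathrm{SSC}\, C^*))
  = \mathrm{RPI} + \ln(L^* h° / C^*)$,
* visual ripeness index (VRPI): the area of the closed radar polygon over
  $m$ normalized quality parameters,
  $$\mathrm{VRPI} = \tfrac{1}{2}\sin\!\frac{2\pi}{m}
    \Big(\sum_{n=1}^{m-1} P_n P_{n+1} + P_1 P_m\Big),$$
  which equals the shoelace area of the polygon with vertex $n$ at radius
  $P_n$ and angle $2\pi(n-1)/m$. The default radar uses SSC, TA, a\*, Fp, Ff
  in that order ($m = 5$); SSC and a\* rise with ripening and are normalized
  forward, $(x-\min)/(\max-\min)$; TA, Fp, Ff fall and are reverse-coded as
  the complement.

Normalization bounds are a modeling decision. `fit_radar_normalizer()`
learns them from a reference set — by default the calibration fruit, so that
test fruit are scored against frozen bounds (no leakage). New fruit may then
fall outside $[0,1]$; the area formula only requires non-negative vertices.

A subtlety worth stating: the area of a pentagon with all vertices at 1 is
$2.5 \sin 72° \approx 2.378$. Batch-mean VRPI values approaching or
exceeding that ceiling therefore cannot arise from min–max normalization
over the same fruit (where batch means sit well inside $(0,1)$); they
require wider *reference ranges* fixed by design. The synthetic orchard
follows that reading: its design trajectories (below) define the reference
bounds (`radar_reference()`), against which a fruit's normalized vertices
equal its latent maturity and the configured batch VRPI targets are
reproduced exactly in the zero-noise limit.

## The synthetic orchard

The generator is a linear-Gaussian latent-maturity model, the simplest
structure under which PLS is well specified. Four weekly harvests (90, 97,
104, 111 days after flowering; 60 quality fruit per batch, 40 more for
storage) are placed on a latent maturity axis $q$:

* Batch positions $P_b = \sqrt{T_b / (2.5 \sin 72°)}$, where $T_b$ are the
  per-batch VRPI targets — with equal radar vertices the polygon area is
  then exactly $T_b$.
* Within-batch spread $\sigma_b$ is derived from the VRPI SD targets via the
  area's sensitivity to $q$.
* Every quality parameter is a monotone affine function of $q$ plus noise,
  with field-plausible trajectories (e.g. SSC 9→13 °Brix, Ff 48→24 N over
  the full latent range). The TA, hue and SPI affine coefficients are
  solved at run time by 4-point least squares so the batch means of RPI,
  IQI and the Streif index track their configured targets (residuals ~1%
  for RPI/IQI at the defaults). SPI is rounded to an ordinal 1–10 grade.
* TA decorrelation: pooled across batches, TA should be nearly uncorrelated
  with the other quality indices. Because TA's between-batch trend follows
  the latent, the within-batch TA component runs *against* the latent with
  a fixed slope (default −0.493, chosen so the two covariance contributions
  cancel at the default targets) plus independent noise. TA remains a
  deterministic-plus-noise function of $(q, \text{batch})$, so its vertex
  of the VRPI stays predictable from spectra.

Spectra are sums of a smooth baseline and Gaussian absorption bands: water
bands near 5150, 5620, 6900, 8310 and 10,300 cm⁻¹, C–H combination/overtone
structure near 4400, 4760 and 11,500 cm⁻¹ and inside 5555–5882 and
8264–8696 cm⁻¹. Band amplitudes are affine in the fruit's SSC, Ff and TA;
water-band amplitudes additionally decline with harvest date (week-to-week
water loss), a *differential* effect that survives scatter correction and
derivatives — a flat baseline shift would be erased by SNV or a first
derivative and would leave the batch signature invisible to the downstream
models. The baseline falls with maturity and harvest date, so mean
absorbance decreases across batches. Per-sample multiplicative/additive
scatter (SDs 0.05 / 0.02) and white noise (SD 0.005 absorbance units,
typical of FT-NIR fruit spectra) complete the noise model.

`inject_outliers()` emulates internally lesioned fruit (broad extra band,
elevated baseline) and returns their ids; dropping them reproduces the
240 − 2 = 238 modeling samples of the study design.

What the generator does *not* emulate: instrument physics (interferograms,
detector nonlinearity), skewed or heavy-tailed quality distributions,
batch-specific scatter structure, and the trigonometric coupling among a\*,
b\*, C\* and h° (color coordinates are generated as independent affine
trends; the hue trajectory is calibrated to the IQI targets rather than to
colorimetric realism). Passing tests therefore demonstrate correctness of
the algorithms and recoverability under the stated noise model — not
instrument-level performance on real fruit.

## Preprocessing

Five pretreatments: Savitzky–Golay smoothing (SG), standard normal variate
(SNV), multiplicative scatter correction (MSC), SNV + 1st derivative, MSC +
2nd derivative. Scatter correction is applied before the derivative — the
conventional reading of "SNV plus first derivative". SG defaults are window
15, polynomial order 2 (order 3 for the second derivative), common
chemometrics practice; derivatives are scaled by the wavenumber step and
edges handled by one-sided polynomial fits. The MSC reference is the
calibration-set mean, frozen into fitted models so test spectra are
corrected against the calibration reference.

## CARS wavelength selection

Competitive adaptive reweighted sampling runs N = 50 Monte-Carlo iterations,
each fitting a PLS model on an 80% subsample of the calibration fruit and
weighting the retained variables by |regression coefficient| on autoscaled
variables (so weights are scale-free). The retained count follows the
exponentially decreasing schedule $r_i = a e^{-k i}$ with $r_1 = 1$ and
$r_N = 2/p$. Enforced reduction and adaptive reweighted sampling are merged
into a single weighted draw *without replacement* of exactly
$\mathrm{round}(r_i p)$ variables: this keeps the retained counts exactly on
the schedule (a draw with replacement would undershoot it) while preserving
the stochastic competitive element. Each subset's RMSECV is measured by
5-fold cross-validation over one fixed seeded fold partition so the trace is
comparable across runs; the subset with minimal RMSECV wins. CARS sees only
the training fruit — selection never touches the test set.

## PLS modeling and validation

Samples are split by the deterministic Kennard–Stone max-min-distance
algorithm (ties toward the lowest index). The quantitative split computes
the 3:1 training size on the sample total *before* outlier removal: 240
collected fruit give round(240 × 3/4) = 180 calibration fruit, and removing
the 2 outliers leaves 58 test fruit — the 180/58 partition of 238 modeled
samples. The classification holdout instead uses ceiling(3n/4) = 179/59.

Regression is single-response NIPALS PLS on mean-centered data, with
coefficients accumulated for every component count (at most 15, the largest
factor count the study design calls for) so one fit serves all model sizes.
The component count minimizes the 5-fold RMSECV; $R^2$ is always the
coefficient of determination $1 - SS_{res}/SS_{tot}$ (not squared Pearson
correlation). Metrics: Rcv²/RMSECV on pooled out-of-fold predictions,
Rp²/RMSEP on the untouched test set.

## Maturity classes and classifiers

Post-ripening quality (a\*, SSC, TA, edible rate, rot rate after 30 d cold
storage plus shelf period) is min–max normalized over the batches (TA and
rot rate reverse-coded), each parameter weighted 0.2; the batch score is the
weighted sum. Each fruit's score is Fs = min–max-normalized VRPI + its
batch's post-ripening score, and the label is a pure step function:
unripe for Fs < 0.8, ripe for 0.8 ≤ Fs < 1.2, over-ripe for Fs ≥ 1.2. (The
three-rule set only reads consistently with "unripe" below 0.8 — higher
scores mean riper fruit.)

Classifier inputs are the CARS-selected wavelengths of the preprocessed
spectra; features are standardized with training-fold statistics only.
The five algorithms and their fixed hyperparameters:

* **LDA** — linear discriminant with the pooled covariance shrunk toward a
  scaled identity; the shrinkage intensity is chosen by seeded internal CV
  on the training data. Plain LDA is unusable here: a few hundred strongly
  collinear wavelengths make the pooled covariance near-singular.
* **NB** — naive Bayes with per-class, per-feature Gaussian *kernel density*
  estimates (normal-reference bandwidth), priors from training frequencies.
* **KNN** — k = 3, cubic Minkowski distance, inverse-squared-distance
  vote weights.
* **SVM** — linear kernel, box constraint 0.5901, one-vs-one multiclass.
* **NN** — one hidden layer of 50 sigmoid units, softmax output,
  cross-entropy loss with L2 penalty 0.00030942, 200 iterations. Training
  uses L-BFGS with analytic gradients; a dense-Hessian optimizer is
  impractical at ~10⁴ weights.

Validation: seeded 5-fold cross-validation (pooled out-of-fold predictions)
and Kennard–Stone holdout. Reports are 3×3 confusion matrices with fixed
class order (over-ripe, ripe, unripe) and classification accuracy
CA = 100 · trace/total, reported to one decimal.

## Numerical choices and degenerate inputs

* All randomness is seeded and restored (`config$seed` drives the
  generators; CV folds, CARS draws and NN initialization take explicit
  seeds), so identical configurations are bit-reproducible.
* Ties: coefficient ranking and Kennard–Stone fall back to the lowest
  index; `which.min`/`which.max` conventions make every argmin
  deterministic.
* Degenerate inputs fail loudly with the offending sample or column named:
  constant spectra (SNV), near-zero MSC slopes (|b| < 1e−10), constant
  radar or post-ripening columns, non-positive index arguments, duplicate
  wavenumbers, schema-version mismatches in model files.
* NIPALS stops early when the residual weight norm falls below 1e−14;
  requested components are clipped (with one warning) when fewer retained
  variables than components remain in late CARS runs.
* Readers reject rather than coerce: ragged rows and non-numeric cells are
  hard errors; writers emit 17 significant digits so round-trips are exact.

## Problem sizes in the test suite

Unit tests run on a reduced wavenumber grid (300 points) where only the
transform algebra matters; the end-to-end properties (VRPI recoverability
Rp² ≥ 0.8, cross-validated classification accuracy ≥ 80%, CARS selection
behavior) are checked at the full study scale — 240 fruit, 2203-point
spectra — over five seeds, a scale chosen to mirror the study design while
keeping a complete run of the suite in the low minutes.

## Known limitations

* The generator's equal-vertex design makes the five radar parameters rise
  in lockstep (latent-driven correlations near 1); real fruit decouple more.
* Reference radar bounds are part of the orchard design; for real data the
  calibration-fitted bounds are the supported default, and absolute VRPI
  levels then depend on the sampled population.
* The unripe/ripe boundary passes through the second batch's upper tail by
  construction (batch score 0.44 plus the calibrated VRPI spread), so a few
  percent of unripe fruit are inherently ambiguous and perfect unripe
  recall is not attainable under these study statistics.
* No wavelength-selection alternatives (SPA, UVE, iPLS), no nonlinear PLS
  variants, no probability calibration for the classifiers.
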