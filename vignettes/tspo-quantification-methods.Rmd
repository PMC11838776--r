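---
title: "Blood-free p_TSPO quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood-free p_TSPO quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Quantifying the 18 kDa translocator protein (TSPO) from dynamic PET is
hard for reasons that are structural, not incidental: arterial sampling is
invasive and error-prone, the free plasma fraction of TSPO tracers is tiny
and inflammation-sensitive, no brain region is free of specific binding
(so no clean reference region exists), the rs6971 polymorphism splits
subjects into affinity classes, and delivery across the blood-brain
barrier varies with inflammatory state. `tspoquant` implements a
quantification strategy that sidesteps blood and reference-tissue
modelling entirely: a logistic regression model is trained to separate
regions with constitutively low TSPO expression from regions with
constitutively high expression, and the fitted probability of belonging to
the high class — `p_TSPO` — becomes the regional index of
neuroinflammatory load.

The model is ordinary logistic regression on region-level feature vectors:

$$\ln\frac{p}{1-p} \;=\; \beta_0 + \sum_{j=1}^{n}\beta_j X_j ,$$

with features

* the regional SUV time-activity curve sampled on a sparse grid
  (default `1.25, 4.5, 13.5, 30, 50, 75` minutes — sparse on purpose, to
  limit collinearity between neighbouring frames),
* the regional delivery rate `K1` (mL/cm^3/min) from a non-invasive
  irreversible one-compartment fit against an image-derived input
  function (IDIF),
* subject covariates: age (years), sex (male = 1), TSPO binding class
  (HAB = 1, MAB = 0), and injected dose over body weight (MBq/kg).

All features are min-max normalized to `[0, 1]`; the bounds are part of
the persisted model bundle so that predictions on new data are exactly
reproducible. At prediction time values outside the training range map
outside `[0, 1]` and are deliberately **not clipped** — clipping would
destroy the monotonicity of the linear predictor exactly where the signal
is most interesting (extreme uptake).

Four modelling assumptions are inherited from the underlying idea:
measured activity is proportional to tracer concentration; the regional
signal is a sum of parenchymal binding, perfusion/extraction and blood
components; covariates explain the constitutive (normative) variability,
so departures flag altered states; and coefficients are shared across the
cortical and cerebellar prediction domain (no region-specific slopes).
The last assumption is the strongest and is the reason predictions are
restricted to cortex and cerebellum; subcortical training regions anchor
the classes but are not part of the reporting domain.

# Pipeline stages and their parameters

## IDIF extraction and the tri-exponential input model

`selectBloodVoxels()` mimics carotid-siphon segmentation on a dynamic
image: voxels are thresholded on a duration-weighted early-window sum
(default window 0-2 min, quantile 0.99) and the surviving candidates are
ranked by the correlation of their TAC with the candidate-mean TAC,
keeping a configurable fraction (default 0.5). Both the correlation
statistic and the cut-off are exposed as configuration because published
descriptions of this procedure leave them open; the procedure is
deterministic with ties broken by voxel order. Voxel indices follow R's
1-based linear indexing convention.

`fitTriExp()` fits the mean blood curve with a piecewise model: a linear
rise from zero to the empirical peak (bolus arrival is not resolved by
the frame grid, and a linear rise is the simplest shape consistent with a
bolus protocol), then a sum of three decaying exponentials. The fit is
weighted least squares with frame-duration weights (longer frames carry
more counts), run by Levenberg-Marquardt in log-parameter space (so
amplitudes and rates stay positive) from a deterministic 36-point grid of
rate initialisations, keeping the best weighted RSS. Rates are stored in
canonical decreasing order; a component whose amplitude collapses to zero
flags an effectively lower-order input. The fitted model has an analytic
running integral, which is what the kinetic stage consumes.

## The kinetic stage

`simulateTissueTac()` solves the serial two-tissue compartment model
analytically for the tri-exponential input: the 2x2 rate matrix is
eigen-decomposed, each exponential mode is convolved with the input in
closed form, and per-frame values are the time-average of the
instantaneous curve over the frame interval (20-point Gauss-Legendre per
frame, split at the input-model kink). The analytic route is verified in
the test suite against an independent stiff ODE solver and against
fine-grid quadrature of the frame averages.

`estimateK1()` implements the 1T1K-IDIF idea: over the first minutes of
the scan the tissue behaves like a single irreversible compartment, so
`C_t(t) = K1 * \int_0^t C_p`, and `K1` is a weighted least-squares slope
with no intercept. Three choices matter:

* **The regressor is the frame-averaged analytic integral** of the fitted
  input, not a quadrature of the sampled blood curve. Early frames are
  15 s wide and the input changes quickly there; the analytic integral
  removes that quadrature error entirely, and makes the estimator exact
  on model-matched data.
* **`vb` is fixed at 0** in the estimator (the irreversible
  single-compartment description has no blood-volume term); a
  two-parameter variant co-estimating a blood fraction is available as an
  off-by-default option, as is nothing-by-default delay handling.
* **The fit window is tracer configuration**: 4 minutes for PBR28-like
  kinetics, 5 minutes for DPA-714/PK11195-like kinetics, never beyond
  10 minutes. The window trades two opposing violations of the
  irreversible approximation: efflux (`k2 > 0`) biases the slope
  increasingly *low* as the window grows, while the unmodelled blood
  fraction inflates the earliest frames and biases it *high* for very
  short windows. At physiological PBR28-like parameters these cross near
  the 4-minute default, which is why the test suite checks both the
  monotone efflux-only bias (with `vb = 0`) and the small net bias at the
  default kinetics (with `vb = 0.03`).

## Fitting, hierarchy and selection

`fitLogit()` is a compact IRLS maximum-likelihood fitter that reports
deviance, standard errors and Wald z statistics, detects perfect
separation (diverging coefficients with vanishing deviance) and names the
offending feature, and accepts an optional ridge penalty (excluded from
the intercept) as a separation rescue. Convergence is declared at a
relative deviance change below `1e-10`, capped at 100 iterations. The
test suite checks it against `glm()` and against a coarse-to-fine grid
minimizer of the deviance surface. Wald statistics are labelled z (not t)
in all output.

`fitHierLogit()` adds a Gaussian random intercept per dataset — the
batch-effect structure expected when cohorts come from different scanners
and reconstruction protocols — fitted by Laplace-approximate maximum
likelihood via `lme4::glmer()` (adaptive quadrature available as a
verification mode through `nAGQ`). Per-dataset modes are centred, with
the residual mean folded into the intercept, so the stored intercept is
the population level; unseen datasets predict at offset 0.

`stepwiseDeviance()` is bidirectional stepwise selection from the
intercept-only model with chi-squared(1) deviance tests (enter at
p < 0.05, remove at p > 0.10 — conventional thresholds, since only the
criterion itself, deviance, is prescribed by the method; forward-only is
a flag). `bootstrapSelection()` stabilises it: 100 bootstrap resamples
drawn **at the subject level** (a subject's regions share covariates and
noise, so row-level resampling would understate variability), tallying
per-feature selection frequencies and retaining features selected in
strictly more than 80% of completed resamples. Resamples that lose one
outcome class are skipped and counted; frequencies are over completed
resamples.

## The evaluation battery

* `rocAnalysis()` sweeps thresholds over the scores; the trapezoidal AUC
  equals the Mann-Whitney concordance (ties at 1/2), which the tests
  verify against a brute-force pairwise count. Because no decision
  threshold is canonical for `p_TSPO`, `rocOperatingPoints()` reports
  both the fixed 0.5 point and the Youden-optimal point, with no claim
  that either matches any published operating point.
* `deltaP()` bins two cohorts' `p_TSPO` values into relative-probability
  histograms (bin width 0.05 on `[0, 1]`; the value 1.0 is folded into
  the last bin) and reports `Delta_P`: 100 times the summed case-minus-
  control deviation over bins whose lower edge is at or above 0.5. The
  "lower edge >= 0.5" convention makes the 0.5 boundary unambiguous.
  Wilcoxon tests are exact for small samples (both groups <= 25), normal
  with tie correction otherwise.
* `iccTestRetest()` computes ICC(A,1) — two-way, absolute agreement,
  single measure — from the mean-squares decomposition, and says so in
  its output, since reliability conventions differ and the form matters.
  Zero between-subject variance yields `NA`, never a fabricated value.
* `expressionConcordance()` uses Spearman rank correlation between mean
  regional `p_TSPO` and the regional expression score: expression maps
  derived from microarray data are ordinal-scale at best (Pearson is
  available as an option).
* `fdrAdjust()` is Benjamini-Hochberg step-up via `p.adjust`.

## The rodent variant

The rat workflow replaces the anatomical prior with a physiological one:
in an intracerebral-LPS lesion model the ipsilateral hemisphere carries a
focal inflammatory lesion while the contralateral side is quiet, so
`hemisphericAucScreen()` compares the trapezoidal AUC of homologous SUV
TACs with a paired t-test across animals and keeps the BH-FDR-significant
regions as training classes (ipsilateral = 1, contralateral = 0). The
predictor set drops age, sex and genotype (standardized in laboratory
animals), and the TAC grid drops the 75-minute point that a 60-minute
acquisition cannot serve. After training, predictors are screened by Wald
test at |z| > 1.96. With four training animals and a histologically clean
lesion the likelihood can be flat enough that no predictor passes; the
pipeline then retains the single most informative predictor (lowest
univariate deviance, near-ties within one chi-squared unit resolved by
the univariate Wald statistic) rather than carrying a full collinear
model whose weights would be arbitrary. Group contrasts (ip-LPS vs
vehicle) are per-region rank-sum tests on the linear predictor — the same
ordering as `p_TSPO`, but immune to double-precision saturation at 0/1 —
with BH-FDR correction.

# The synthetic-data generator

Nothing in the human datasets this method was designed for is publicly
depositable, so the package carries a generative model that reproduces
the *statistical structure* the method assumes, at desk scale:

* **Regions.** 25 regions: bilateral thalamus/pallidum analogues as the
  high-expression training class, occipital and dorsal cerebellar
  analogues as the low class, and a spread of cortical/cerebellar regions
  as the CC prediction domain. The expression map is a pure function of
  the roster (high band 0.85-1.0, low band 0.02-0.14, middle band
  0.20-0.62), so changing a seed changes noise realisations but never the
  ground-truth structure.
* **Kinetics.** Two-tissue parameters in PBR28-like ranges: regional
  `K1` 0.10-0.125 mL/cm^3/min, `k2 = 0.04`, `k4 = 0.02` (1/min),
  `vb = 0.03`, and binding `k3 = 0.02 + 0.13 * expression` so that
  binding follows the expression map by construction. Genotype acts as a
  multiplicative factor on `k3` (MAB = 0.5 x HAB — a configurable
  stand-in, with no claim of matching in-vivo affinity ratios), age as a
  mild slope (+0.4%/year around 40), sex as a small factor (female
  0.95), and a global `bindingScale` emulates disease (+30%) or
  target blocking (-60%).
* **Variability.** The TSPO field's hallmark is large unexplained signal
  variability; the generator encodes it as a per-subject log-normal
  global binding factor (sd 0.3) and per-region jitter (sd 0.15), plus
  log-normal input-amplitude (sd 0.10) and delivery (sd 0.05) jitter.
  Without these the low/high classes separate almost perfectly and every
  downstream contrast saturates, which real TSPO data never do.
* **Acquisition.** The 26-frame, 90-minute binning (8x15 s, 3x1 min,
  5x2 min, 5x5 min, 5x10 min) and a 23-frame 60-minute variant; dataset
  batch effects as additive log-scale sensitivity factors (defaults 0,
  -0.15, +0.15), which is exactly the structure the random-intercept
  model absorbs; three datasets of 72/27/26 subjects by default.
* **Noise.** Zero-mean Gaussian with variance proportional to activity
  over frame duration (the standard frame-count heuristic), scaled so
  late frames sit at roughly 5-10% coefficient of variation, and floored
  at zero as iterative (OSEM-style) reconstructions enforce.

What the generator does **not** emulate — and what green tests therefore
do not certify on real data: resolution effects and partial volume,
scatter/attenuation residuals, motion, metabolite kinetics in blood,
regionally varying covariate effects, and any real scanner's noise
correlation structure. The generator exists to make every pipeline stage
testable against known ground truth, not to claim anatomical realism.

# Numerical choices

* Exponential convolutions use closed forms with series fallbacks for
  small `a*t` (avoiding catastrophic cancellation) and a limit branch for
  nearly-equal rates; degenerate eigenvalue pairs of the rate matrix are
  split by a 1e-8 relative perturbation.
* Frame averages use 20-point Gauss-Legendre per frame (nodes from the
  Golub-Welsch eigenproblem, cached), split at the input-model peak.
* Min-max normalization refuses degenerate (min = max) features; its
  bounds default to the labelled training rows, with a pooling switch
  (`boundsFrom = "all"`), because pooling conventions for "all available
  data" are ambiguous in practice.
* TAC tables are written with 17 significant digits so write/read
  round-trips are bit-exact.
* Stepwise selection and the bootstrap save and restore the RNG state;
  every stochastic routine takes an explicit seed.
* The stratified 80/20 split uses composite strata (sex x genotype x
  age-dichotomy x dataset), largest-remainder allocation of test slots
  and seeded within-stratum shuffles; age exactly 30 goes to the older
  stratum.

# Problem sizes

The shipped tests and the acceptance script run the full human pipeline
on the default 125-subject, 25-region cohort (bootstrap selection
included), disease/blocking contrasts on 20-subject cohorts, the
hierarchical recovery study on 2000 rows across three datasets, and the
rat pipeline on 4 + 8 + 8 animals — sizes chosen to mirror the cohort
structure the method targets while keeping a complete run in the order of
a minute on one CPU.

# Known limitations

* The hierarchical fit uses a single scalar random intercept; crossed or
  nested batch structures (site x scanner x protocol) are out of scope.
* `p_TSPO` is a relative, training-anchored index: it is only comparable
  across scans quantified with the same model bundle, and a bundle
  trained on one tracer's kinetics does not transfer to another without
  retraining.
* The K1 stage inherits every limitation of IDIF methods — no metabolite
  correction, no plasma/whole-blood ratio — which is acceptable only
  because `K1` enters as a covariate, not as an absolute quantification
  target.
* Voxel-wise parametric mapping and region-varying coefficients are
  deliberately not implemented.
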