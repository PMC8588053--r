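---
title: "Classifying membrane pore sizes from AFM measurements: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying membrane pore sizes from AFM measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmpore)
```

## The problem

Regenerated-cellulose dialysis membranes are sold by molecular-weight
cutoff (MWCO) — the solute mass above which the membrane retains most
molecules. Whether an atomic force microscope (AFM) can *distinguish*
membranes of different MWCO from their measured pore-radius
distributions is a question about overlapping, strongly right-skewed
distributions measured with instrument error, not about mean pore size
alone. `afmpore` implements a complete statistical pipeline for that
question:

1. physical reference radii (the Stokes radius implied by the MWCO) and
   the measurement-accuracy errors against them;
2. quality control — periodic instrument drift and location-to-location
   environmental shifts;
3. normality screening and Gamma modelling of the skewed radii;
4. a parametric-bootstrap classification study: Monte-Carlo replicate
   datasets drawn from fitted Gammas, hold-out logistic classification,
   ROC/AUC/Youden/accuracy metrics;
5. a test-size sweep that finds the smallest dataset fraction giving a
   stable classifier, and hence a projected reduction in AFM scan time.

## Physical reference models

The theoretical pore radius of an MWCO standard treats the retained
solute as a solid sphere of solid-phase density
$\rho$ (g/cm$^3$):

$$ r_p = \left( \frac{3 M_w}{4 \rho \pi N_A} \right)^{1/3}, $$

converted to nm. For the three standards used throughout:

```{r}
round(stokes_radius(kda(c(50, 100, 1000))), 1)
```

Accuracy errors are the relative (%) and absolute (nm) deviations of a
measured mean radius from $r_p$; they are carried at full precision and
rounded only for display (three significant figures and whole nm,
respectively). Because cellulose hydrogels swell in solution, the
package can also scan a hypothetical swelling ratio SR, replacing the
reference with $r_p (1 + \mathrm{SR})$; the absolute error is V-shaped
in SR with its minimum at $\mathrm{SR}^* = \bar{x}/r_p - 1$, so a
common SR across membranes would reveal itself as a shared descending
branch.

## Quality control

**Drift.** Periodic stage drift would imprint a periodic signal on the
radii in acquisition order. `fit_fourier()` fits
$a_0 + \sum_k a_k \cos(k\omega t) + b_k \sin(k\omega t)$ by least
squares over both the coefficients and the fundamental frequency
$\omega$ (for fixed $\omega$ the model is linear, so the search is a
20-point log-spaced multistart over fundamentals in $(1/n, 1/2)$ cycles
per index, with local refinement of the best brackets to tolerance
1e-9). The periodicity indicator is the adjusted $R^2$ with
$p = 2h + 2$ fitted parameters ($h$ harmonics, default 2, plus the
constant and the frequency). Values near 1 indicate periodic structure;
on independent noise the adjusted $R^2$ stays well below 0.5. The drift
flag threshold defaults to 0.8: far above what iid data produce (the
false-positive rate at $n = 60$ is below 5%), and reached reliably once
the drift amplitude is about four noise standard deviations. At an
amplitude of three standard deviations the *population* adjusted $R^2$
is itself approximately 0.8, so the flag is genuinely borderline there
— the tests assert clear periodic structure (adjusted $R^2 > 0.6$) at
3σ and reliable flagging at 4σ.

With `robust = TRUE` the coefficients are re-estimated by 10 rounds of
iteratively reweighted least squares with Tukey bisquare weights
(tuning constant 4.685) at the selected frequency, and the reported
$R^2$ uses the bisquare-weighted sums of squares: a robust fit should
not be scored on the outliers it deliberately down-weighted.
Acquisition index ($t = 1, \dots, n$) stands in for time, which is the
only ordering information a scan series carries.

**Environmental shifts.** Progressive drying (tapping mode) or
continued swelling (fluid mode) would shift radii between scan
locations. `location_shift_test()` applies the Kruskal–Wallis rank test
(via `stats::kruskal.test`, with midranks and tie correction) to radii
grouped by location; a non-significant p-value supports a stable
sample.

## Normality screening and the Gamma model

Pore-radius distributions are strongly right-skewed, so Gaussianity is
screened before any parametric comparison. The Jarque–Bera statistic

$$ JB = n \left( \frac{b_1^2}{6} + \frac{(b_2 - 3)^2}{24} \right) $$

uses the *uncorrected* central-moment estimators of skewness $b_1$ and
plain kurtosis $b_2$ (a Gaussian has $b_2 = 3$). Both choices are
deliberate: the uncorrected estimators are what reproduce the reference
statistics for the fluid-mode datasets exactly from their printed
moment summaries, and storing kurtosis plain (rather than as excess)
keeps the $b_2 - 3$ term meaningful.

The asymptotic $\chi^2_2$ critical value (5.99 at $\alpha = 0.05$) is
noticeably anti-conservative at scan-series sample sizes, so
`jb_critical()` estimates the finite-sample null quantile by Monte
Carlo — about 5.1 at $n = 60$ and 5.7 at $n = 304$ with $10^5$
replicates. Using these criticals restores the nominal 5% type-I error.

`pairwise_discrimination()` gates on this screen: if both samples pass,
a Brown–Forsythe/Levene check (absolute deviations from the group
*median*, robust to residual skew; the centering is our choice, as only
"Levene" is conventionally specified) selects a pooled or Welch
t-test; otherwise the comparison is the rank-based Kruskal–Wallis test.
No multiple-testing correction is applied, matching the study design
this pipeline mirrors.

For simulation, radii are modelled as Gamma$(a, b)$ (shape, scale).
`gamma_fit_mle()` maximizes the likelihood by Newton iteration on the
profile equation $\log a - \psi(a) = \log \bar{x} - \overline{\log x}$
(method-of-moments start, relative tolerance 1e-10, at most 200
iterations; the scale is then $\bar{x}/a$). `gamma_fit_moments()`
instead inverts the moment identities $\mathrm{mean} = ab$,
$\mathrm{skewness} = 2/\sqrt{a}$ — this is how a reported (mean,
skewness) pair is turned into a simulable distribution when raw data
are unavailable. Skewness, not kurtosis, is used for the inversion
because the Gamma family ties skewness directly to the shape; the
reported kurtosis then serves as a model-adequacy diagnostic rather
than a constraint.

## Classification and the bootstrap study

The classifier is a univariate logistic regression
$\mathrm{logit}(p_i) = \beta_0 + \beta_1 x_i$ on pore radius, fitted by
Newton–Raphson with step-halving to a gradient norm below 1e-8. The
positive class is always the larger-MWCO membrane, so $\beta_1 > 0$ is
the expected sign. With one covariate the MLE is infinite exactly when
the classes do not overlap; such separated fits are flagged, their
coefficients capped at $|\beta| \le 50$, and a warning raised — the
capped fit still ranks observations correctly, so ROC analysis
proceeds.

`roc_curve()` places cutoffs at midpoints between distinct scores
(plus $\pm\infty$ sentinels), calling an observation positive when its
score is at or above the cutoff. The trapezoidal AUC then equals the
midrank Mann–Whitney estimate of $P(X_\text{pos} > X_\text{neg})$
exactly, which the tests assert against an independent rank-based
oracle. The Youden index here is the **halved** convention
$Y = \max_i (Se_i + Sp_i - 1)/2$, bounded by 0.5 for a perfect
classifier; the conventional $Se + Sp - 1$ is available via
`halved = FALSE`. Ties in the maximizer resolve toward the lower
cutoff. The AUC strength scale is categorical: high $[0.8, 1]$, medium
$[0.7, 0.8)$, low $< 0.7$, with boundaries resolved upward.

**Split direction.** `holdout_split()` is stratified per class with
per-class evaluation count `round(eval_fraction * n_class)`
(round-half-to-even, R's default). The pipeline's convention is to
*evaluate* on the large partition (default 80%) and *train* on the
small remainder: with 42 pores per class this yields the 34:8
evaluation:training split that anchors the test-size arithmetic below.
The conventional direction is available by passing
`eval_fraction = 0.2`.

**Bootstrap replication.** `run_pair_classification()` draws
`n_datasets` (default 10) independent two-class datasets from the
configured Gammas, splits each, fits, scores, and aggregates AUC,
accuracy (at the replicate's Youden-optimal cutoff on the evaluation
partition, by default; `cutoff_rule = "half"` uses probability 0.5),
Youden index and coefficients as mean ± SD over replicates. For
well-separated classes the replicate SD is an order of magnitude below
the mean.

**Test-size sweep.** `sweep_test_size()` scales the *total* per-class
dataset to `round(f * n_class)` for each fraction `f` and repeats the
study. Scaling the total (rather than only the training part) is what
makes `f = 0.7` at class size 60 produce the 34:8 split. Each fraction
uses its own seed substream, so adding or removing fractions does not
perturb the others. `select_optimal_fraction()` applies a two-fold
rule: the smallest `f` whose mean AUC changes by at most `slope_tol`
(default 0.01) to the next fraction *and* stays above `auc_floor`
(default 0.7) after subtracting one SD. The last fraction satisfies the
slope condition vacuously. Since scan time is approximately linear in
the number of pores sampled, fraction `f` projects a
`100 * (1 - f)` % reduction in AFM usage time.

`agreement_check()` compares an AUC computed on a raw dataset with the
bootstrap aggregate, declaring agreement within `k` (default 2)
standard deviations of the mean.

## The synthetic-data generator

`make_membrane_dataset()` produces measurement series with the
statistical structure the analysis assumes: iid Gamma radii, a balanced
block assignment to scan locations in acquisition order, and optional
injected perturbations (sinusoidal drift, per-location offsets,
multiplicative outliers) that serve as positive controls for the QC
screens. Positivity is preserved by *resampling* the base draw of any
pore whose perturbed radius would be non-positive — truncation would
pile probability mass at zero and bias the moments.

The six presets of `membrane_presets()` encode the study conditions the
pipeline was built around: three MWCOs imaged in tapping mode (60 pores
over 5 scan locations, 12 per location) and fluid mode (304 pores over
4 locations, 76 per location), each with its reported mean and
skewness mapped to a Gamma via the moment inversion:

```{r}
membrane_preset_params()[, c("preset", "n", "mean_nm", "skewness",
                             "shape", "scale")]
```

What the generator does *not* emulate: tip-contamination physics,
resolution loss below ~5 nm, correlated neighbouring pores, or any
multimodality — its samples are exactly Gamma. Passing tests therefore
demonstrate that the pipeline's statistics behave correctly under the
model it assumes, not that real AFM data satisfy that model. One
consequence worth knowing: inverting the printed *moments* gives much
weaker class separability than the study's own fits to raw
measurements (for the fluid 1000 kDa preset the reported skewness 4.776
implies shape 0.175, concentrating mass near zero), so preset-based
AUCs are far lower than published ones. Reproducing those AUCs would
require the raw per-pore data and is out of scope; the pipeline's
correctness is instead established on synthetic fixtures with known
truth.

## Numerical choices and degenerate inputs

* Radii are radii in **nm** everywhere internally; molecular weights in
  g/mol with a `kda()` convenience converter.
* Constant data: moment summaries, Gamma fits and drift fits raise
  degenerate-input errors; a Kruskal–Wallis test on all-identical
  values is defined as $H = 0$, $p = 1$.
* Reproducibility: every stochastic entry point takes a seed and
  restores the caller's RNG state; nested substreams (master →
  fraction → replicate) come from `sample.int(2^31 - 1)` draws.
* The Youden tie-break, the upward category boundaries, and
  round-half-to-even split counts are all deterministic and tested.
* Known approximation limits: the $\chi^2$ p-value of the
  Kruskal–Wallis test deviates from the exact permutation p by more
  than 0.05 for some rank configurations at total $n \le 8$ (the
  permutation distribution is discrete); agreement is good in the
  rejection-relevant tail. Exact inference at such sizes should use
  enumeration directly.

## Problem sizes used by the test suite

The suite exercises the pipeline at the native study sizes (60 and 304
pores per class, 10 bootstrap replicates), with $10^5$-draw samples for
parameter-recovery checks, $10^5$ Monte-Carlo replicates for JB
critical values, and 20–50 master seeds for trend properties (SD
shrinkage across the sweep, detection power, calibration). These sizes
give comfortable statistical resolution for every asserted margin while
keeping a full run around half a minute.

## Limitations

* The logistic classifier is univariate and binary by design; three-way
  MWCO classification is out of scope.
* Only the Gamma family is supported as the skewed model.
* The drift model is a finite Fourier series with a single fitted
  fundamental; aperiodic drift (a slow monotone trend) is better
  caught by the location-shift screen when locations are scanned
  sequentially.
* Measurement files use one strict CSV dialect (see
  `read_measurements()`) to avoid silent unit errors; instrument-native
  AFM formats are not parsed.
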