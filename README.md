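# afmpore

Statistical pipeline for deciding whether nanoporous regenerated-cellulose
dialysis membranes of different molecular-weight cutoff (MWCO) can be told
apart from atomic force microscopy (AFM) pore-radius measurements — and for
finding how few pores need to be scanned to do it.

AFM pore-radius distributions on these membranes are strongly right-skewed
and overlap heavily between MWCO grades, so the package combines:

* **Physical references** — the theoretical Stokes radius of an MWCO
  standard, `r_p = (3 M_w / (4 ρ π N_A))^(1/3)` (2.7 / 3.4 / 7.3 nm for
  50 / 100 / 1000 kDa), measurement-accuracy errors against it, and a
  hydrogel swelling-ratio error scan.
* **Quality control** — periodic instrument drift via least-squares Fourier
  fits with a fitted fundamental frequency (adjusted R² as the periodicity
  indicator, optional bisquare-robust weighting), and environmental shifts
  across scan locations via the Kruskal–Wallis rank test.
* **Normality screening** — the Jarque–Bera statistic
  `JB = n (b1²/6 + (b2 − 3)²/24)` on uncorrected moment estimators, with
  finite-sample Monte-Carlo critical values (≈ 5.1 at n = 60, ≈ 5.7 at
  n = 304, vs the asymptotic 5.99), gating a parametric (Levene + t-test)
  or non-parametric (Kruskal–Wallis) two-sample comparison.
* **Gamma modelling** — maximum-likelihood shape/scale fits (profile-
  likelihood Newton) and a moment inversion `(mean, skewness) → (a, b)`
  for simulation from reported summaries.
* **Parametric-bootstrap classification** — Monte-Carlo replicate datasets
  from the fitted Gammas; per replicate a stratified hold-out split
  (evaluate on 80%, train on 20%), a Newton-fitted logistic model
  `logit(p) = β0 + β1·x`, and ROC analysis: trapezoidal AUC (provably equal
  to the midrank Mann–Whitney statistic), the halved Youden index
  `max (Se + Sp − 1)/2`, and accuracy at the Youden-optimal cutoff.
* **Test-size optimization** — a sweep of dataset fractions 10–100% with a
  two-fold selection rule (AUC plateau + AUC − SD above 0.7), projecting a
  `100·(1 − f)` % reduction in AFM scan time (30% at f = 0.7, 20% at
  f = 0.8).

A synthetic-data module generates measurement sets with the assumed
structure (Gamma radii, scan-location blocks, optional injected drift /
shifts / outliers) including six presets matching the study's sampling
design: 60 pores over 5 locations (tapping mode) and 304 pores over 4
locations (fluid mode) per membrane.

## Worked example

Two membranes whose pore-radius distributions are well separated
(Gamma means 8 nm and 20 nm):

```r
library(afmpore)

ga  <- gamma_params(16, 0.5)   # smaller-MWCO class: mean 8 nm,  sd 2
gb  <- gamma_params(16, 1.25)  # larger-MWCO class:  mean 20 nm, sd 5
cfg <- pair_config(ga, gb, n_a = 60, seed = 42)

run_pair_classification(cfg)
#> Replicate hold-out classification (10 datasets):
#>   AUC      0.9954 +/- 0.0043  (high)
#>   Accuracy 0.978 +/- 0.017
#>   Youden   0.478 +/- 0.017
#>   beta0    -38.0200 +/- 19.2995
#>   beta1    3.5199 +/- 1.9090
#>   (7 replicate(s) hit separation; coefficients capped)
```

Mean AUC 0.995 ("high" on the categorical scale) with a replicate SD two
orders of magnitude smaller: the pair is reliably classifiable. The halved
Youden index approaches its 0.5 ceiling, and with classes this far apart
most 12-pore training partitions are completely separated, so those
logistic fits are flagged and capped — the ranking, and hence the ROC, is
unaffected. Sweeping the test size:

```r
sw <- sweep_test_size(cfg)
sw[, c("fraction", "n_eval_a", "n_train_a", "auc_mean", "auc_sd")]
#>    fraction n_eval_a n_train_a auc_mean auc_sd
#> 1       0.1        5         1   0.8920 0.3005
#> 2       0.2       10         2   0.9990 0.0032
#> 7       0.7       34         8   0.9952 0.0054
#> 10      1.0       48        12   0.9943 0.0063
#> # ... (fractions 0.3-0.9 omitted here)

f <- select_optimal_fraction(sw)
c(fraction = f, scan_time_reduction = scan_time_reduction(f))
#> fraction scan_time_reduction
#>      0.2                  80
```

At fraction 0.7 the per-class split is 34 evaluation : 8 training pores —
the arithmetic the pipeline's split convention is anchored to. For this
easy pair the selection rule already accepts 20% of the data, projecting an
80% scan-time saving; for realistic overlapping membranes the selected
fraction is much larger or no fraction qualifies.

Quality control on a synthetic preset:

```r
sets <- membrane_presets(seed = 42)
m <- sample_moments(sets$fluid_1000$values)
m
#> n = 304, mean = 18.17, skewness = 5.545, kurtosis = 45.19
jarque_bera(m, critical_value = 5.7)
#> Jarque-Bera: JB = 2.41e+04 (critical 5.7) -> normality rejected
location_shift_test(sets$fluid_1000)
#> Kruskal-Wallis: H = 1.289, df = 3, p = 0.7319
```

Normality is rejected overwhelmingly (hence the Gamma route), while the
location test finds no environmental shift — as expected for a clean
synthetic sample.

A thin command-line front end over the same functions lives at
`inst/cli/afmpore.R` (subcommands `simulate`, `qc`, `classify-pair`,
`sweep`).

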