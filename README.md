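# sdnamdyn

Serum soluble DNAM-1 (sDNAM-1, shed CD226) rises and falls after
allogeneic hematopoietic stem-cell transplantation as three cell
populations secrete it: alloreactive donor lymphocytes (a transient
burst), non-alloreactive donor lymphocytes (persistent, reconstituting),
and the recipient's residual pre-transplant pool (decaying). The share
of donor-derived exposure contributed by the transient source tracks
the risk and severity of acute graft-versus-host disease (aGVHD), but
an ELISA measures only the total — the decomposition must come from a
dynamical model. `sdnamdyn` implements that model, the per-patient
fitting machinery, and the downstream biomarker statistics, for
biostatisticians and transplant immunologists working with longitudinal
serum biomarker panels.

## The model and the biomarker

Concentrations (pM) from the day of transplant follow

    dx1/dt = lam * t^(k-1) exp(-t/theta) / (Gamma(k) theta^k) - mu * x1     x1(0) = 0
    dx2/dt = (r - mu) * x2 * (1 - x2/N)                                     x2(0) = x2_0
    dx3/dt = -mu * x3                                                       x3(0) = x3_0

— a gamma-kernel production term with first-order clearance for the
transient source, logistic growth for the persistent source, and
exponential decay for the residual, all sharing one clearance rate
`mu` (eight parameters in total; serum half-life = `log(2)/mu`). The
two-source restriction fixes `lam = 0` (five parameters). Each
patient's series is fitted by bounded multistart Levenberg–Marquardt
least squares and the two variants are compared with the least-squares
AIC, `n log(RSS/n) + 2p`.

The biomarker is the transient share of donor-derived exposure over the
first `n` days,

    R_day_n = 100 * AUC(x1; 0..n) / (AUC(x1; 0..n) + AUC(x2; 0..n))   (%)

evaluated at horizons 20/30/40/50 by default, compared between GVHD
groups (Welch t, Wilcoxon), and assessed by ROC analysis with the
closest-to-(0,1) cutoff.

Because no patient-level data are deposited, the package ships a
synthetic-cohort generator (`generate_cohort()`) reproducing the study
design — 67 patients (48 GVHD+), sparse irregular sampling over days
−7 to ~249, 10% lognormal ELISA noise, a ~12.5-day mean half-life, and
group-calibrated transient shares — with full ground truth for
validation.

## Worked example

```r
library(sdnamdyn)

# a synthetic patient with a pronounced day-8 transient burst
p <- sdnam_params(lam = 400, k = 3, theta = 4, mu = 0.08,
                  r = 0.15, N = 25, x2_0 = 5, x3_0 = 10)
compute_rday(p, day_n = c(20, 30, 40, 50))
#> # A tibble: 4 x 5
#>   patient_id day_n auc_x1 auc_x2 r_day_n
#>   <chr>      <dbl>  <dbl>  <dbl>   <dbl>
#> 1 <NA>          20  2257.   170.    93.0
#> 2 <NA>          30  3624.   318.    91.9
#> 3 <NA>          40  4360.   503.    89.7
#> 4 <NA>          50  4710.   716.    86.8
```

`r_day_n` is the percentage of donor-derived sDNAM-1 exposure
attributable to the alloreactive transient source: this patient's
donor signal is ~93% burst-driven over the first 20 days, drifting down
as the persistent source accumulates — the profile the model associates
with aGVHD.

```r
# a small end-to-end run: simulate, fit both variants, select, evaluate
cohort <- generate_cohort(cohort_config(n_patients = 10, n_pos = 6, seed = 3))
res <- run_pipeline(cohort$measurements, cohort$metadata,
                    options = fit_options(n_starts = 10, n_hops = 6, seed = 1))
res
#> <sdnam_pipeline> 10 patients in, 10 included, 10 fitted
#>   three-source preferred: 6/10 (60.0%), binomial p = 0.754
#> # A tibble: 4 x 12
#>   horizon n_neg n_pos mean_neg mean_pos   sd_neg sd_pos diff_mean ci_low ci_high
#>     <dbl> <int> <int>    <dbl>    <dbl>    <dbl>  <dbl>     <dbl>  <dbl>   <dbl>
#> 1      20     4     6 1.86e-10     47.1 3.02e-10   44.8      47.1  0.118    94.2
#> 2      30     4     6 1.36e- 7     51.1 2.33e- 7   44.6      51.1  4.29     98.0
#> 3      40     4     6 9.68e- 6     52.4 1.69e- 5   44.7      52.4  5.53     99.4
#> 4      50     4     6 1.96e- 4     52.4 3.38e- 4   44.6      52.4  5.66     99.2
```

In this draw all four GVHD-negative patients happen to be burst-free
(transient share essentially zero), while the positive group's mean
share sits ~47–52%; `res$roc` holds
the corresponding AUCs, cutoffs and confusion counts. `autoplot()` on a
fitted patient draws the decomposed trajectories; `plot_rday_groups()`
reproduces the grouped boxplots.

Published count statistics are one call away:

```r
binomial_preference_test(47, 67)   # p = 0.00131, 70.1% (57.7–80.7%)
fisher_2x2(matrix(c(12, 7, 32, 16), 2, 2))  # p = 0.783
```

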