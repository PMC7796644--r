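# maintwce

Time-varying cumulative-exposure Cox models for maintenance randomized
trials.

## The problem

Maintenance trials in metastatic colorectal cancer randomize patients to
continue or stop a targeted antibody (5 mg/kg every two weeks, one
"cure" = one dose unit) during chemotherapy-free intervals (CFIs).
Over several years of follow-up, actual drug exposure drifts far from
the randomized assignment — missed and reduced cures, discontinuations,
re-treatment sequences in both arms — so the conventional
intention-to-treat (ITT) hazard ratio mixes the prognosis of maintenance
patients who never took the drug with that of heavily exposed ones.

`maintwce` implements a re-analysis strategy for this setting, aimed at
biostatisticians and pharmaco-epidemiologists: replace the arm indicator
with time-varying cumulative-exposure metrics inside counting-process
Cox models, compare fits by AIC, and estimate how the effect of a dose
decays with time since intake.

## The models

For doses $X_i(t_k)$ received strictly before $t$, the package computes
five exposure metrics:

| metric | definition |
|---|---|
| CE | updated cumulative dose $\sum_{t_k<t} X_i(t_k)$ |
| CEQ | risk-set tertile/quartile categories of CE(t), recomputed at every event time |
| StCE | risk-set z-score of CE(t) |
| TBC | theoretical blood concentration $\sum_{t_k<t} X_i(t_k)\,0.5^{(t-t_k)/h}$, half-life $h = 20$ d |
| WCE | weighted cumulative exposure $\sum_{t_k<t} X_i(t_k)\,w(t-t_k)$, $w$ an unpenalized cubic B-spline estimated from the data |

Each enters a multivariable Cox model (`survival::coxph` under the hood)
with fixed and carried-forward time-varying confounders; the WCE weight
function gets a delta-method pointwise band, an AIC-selected exposure
window (120 / 365 / 730 days), and hazard-ratio curves for clinically
interpretable dosing patterns. A Grambsch–Therneau global test (classical
scaled-Schoenfeld form) checks proportional hazards. Because the original
patient data are not public, a synthetic-trial generator with a known
exposure effect makes every stage testable end to end.

## Worked example

Simulate a 488-patient maintenance trial whose deaths are driven by a
protective concentration effect (true log HR −0.22 per dose unit,
half-life 20 days), landmark it at 6 months, and compare the ITT model
with the concentration model:

```r
library(maintwce)

cohort <- simulate_trial(sim_config(), true_model(), seed = 42)
lmc <- shift_baseline(cohort$patients, cohort$doses,
                      cohort$covariates, cohort$outcomes)
lmc
#> <landmarked_cohort> 389 patients analyzed, 99 excluded (landmark 182 d)
#>                    category  n
#>        died before baseline 40
#>  progressed before baseline 50
#>        lost before baseline  1
#>          missing covariates  8

tab <- build_counting_process(lmc)
tab <- add_exposure_column(tab, lmc$doses, "tbc", "overall")
itt <- fit_cox_tv(tab, c("arm", "age_group", "sex", "who_ps"))
tbc_fit <- fit_cox_tv(tab, c("arm", "tbc_overall", "age_group", "sex", "who_ps"))
tbc_fit
#> <cox_fit> 303 events / 84977 intervals; k = 6; loglik = -1614.775; AIC = 3241.549
#>            term    coef     se    HR CI_low CI_high        p
#>  armmaintenance -0.0656 0.1204 0.936  0.740   1.186 5.86e-01
#>     tbc_overall -0.2661 0.0828 0.766  0.652   0.901 1.31e-03
#>  age_group65-74  0.0891 0.1329 1.093  0.842   1.419 5.03e-01
#>   age_group>=75  0.2990 0.1531 1.348  0.999   1.821 5.09e-02
#>            sexM -0.0123 0.1228 0.988  0.777   1.257 9.20e-01
#>          who_ps  0.3964 0.0829 1.486  1.264   1.749 1.72e-06

aic(itt) - aic(tbc_fit)
#> [1] 8.861013
```

The arm indicator alone sees nothing (HR 0.94), while the concentration
term recovers the protective effect (−0.266 ± 0.083 against a true
−0.22, HR 0.77 per circulating dose unit), and dropping it costs about
9 AIC points — a loss of fit approaching the scale where 10 points is
deemed important. The implied risk reduction for a patient holding
8 mg/kg in circulation, with a unit (per mg/kg) hazard ratio of 0.77:

```r
hr <- hr_for_dose_pattern(pattern = dose_history(0, 16), t_grid = 20,
                          unit_loghr = log(0.77), half_life = 20)
round(100 * (1 - hr$hr))
#> [1] 88
```

## The analysis workflow

`analysis/` contains the numbered drivers that reproduce the full
re-analysis on a synthetic cohort, writing their tables under `results/`:

1. `01_simulate.R` — generate and export the cohort CSVs (+ segregated truth)
2. `02_landmark_build.R` — landmark, build the counting-process table, append exposures
3. `03_model_suite.R` — fit the nine-model comparison suite, export `model_comparison.csv`
4. `04_weight_function.R` — AIC window selection, weight function with band, dose-pattern HR curves
5. `05_sensitivity.R` — baseline-only adjustment and recent-dose-indicator variants

Run them in order with `Rscript analysis/01_simulate.R`, etc.

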