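# lifehorizon

Lifetime outcomes for disease cohorts reconstructed from
health-insurance claims: lifetime risk, life expectancy after
diagnosis, expected years of life lost (EYLL), and survival-weighted
discounted lifetime healthcare costs.

Claims databases follow patients for a decade at most, while
prevention policy needs lifetime answers. `lifehorizon` closes that
gap with a semi-parametric survival extrapolation: the cohort's
Kaplan–Meier curve is compared with *matched referents* — lifetimes
simulated by Monte-Carlo walks of a national life table, matched to
each patient's sex, age and calendar year at index — through the
logit survival ratio

W(m) = logit( S_cohort(m) / S_referent(m) ),

which a rolling-over algorithm (trailing-window OLS of W on month,
predict one month, reconstruct S = expit(W)·S_ref, roll forward)
extends to the lifetime horizon. From the extrapolated curve:

- **LE** = ∫ S_cohort dt, **LE_ref** = ∫ S_referent dt,
  **EYLL** = LE_ref − LE (all trapezoidal on a monthly grid);
- **lifetime cost** = Σ_m S(m)·c(m)·(1+r)^(−m/12) per payment stream
  (insurer / copayment) at 0/3/5% annual discounting, with monthly
  mean costs extrapolated by the same rolling scheme on the
  log(1+cost) scale;
- **lifetime risk** = CIR_18–84 = 1 − exp(−Σ_i IR_i·ω_i) over
  thirteen age bands (18–24 then 5-year bands to 80–84), with
  sampling-fraction scaling and a prevalence-adjusted sensitivity
  variant.

A cohort builder reproduces the standard claims
inclusion/exclusion cascade (washout for prevalent cases,
hospitalization + CT/MRI requirement, age accuracy, subtype
consistency) with a conserving exclusion ledger, comorbidity flags
and a claims-based severity index. Because real databases of this
kind are access-restricted, a synthetic claims generator with
analytically known ground truth (death process = life-table hazard ×
piecewise-constant excess; lognormal monthly costs with an
end-of-life surge) makes the whole pipeline testable; the bundled
stroke-subtype scenarios (SAH/ICH/NIH/CI) mirror the composition of a
published first-ever-stroke cohort.

## Worked example

```r
library(lifehorizon)

lt     <- generate_life_table(2002, 2016)        # Gompertz-Makeham national-style table
scen   <- stroke_subtype_scenarios(seed = 1)$ICH # n = 2022 ICH-like cohort, indexed 2006
sim    <- generate_cohort(scen, lt)              # claim lines + ground truth
cohort <- build_cohort(sim, window = c(scen$admin_start, scen$admin_end))
cohort$ledger
#>         candidates  prevalent_washout no_hospitalization         no_imaging
#>               2022                  0                  0                  0
#>     inaccurate_age    inconsistent_dx           retained
#>                 53                  0               1969

est <- estimate_lifetime(cohort, lt, n_replicates = 100, seed = 2)
round(c(LE = est$LE, LE_ref = est$LE_ref, EYLL = est$EYLL), 2)
#>     LE LE_ref   EYLL
#>  19.68  22.29   2.61
```

The matched referents would live 22.29 more years on average; the
cohort's extrapolated mean survival after diagnosis is 19.68 years,
so each case loses 2.61 expected years of life. Costs and the
split-sample validation follow the same objects:

```r
profile <- extrapolate_costs(monthly_mean_costs(cohort), est$index_curve)
cost    <- lifetime_cost(profile, est$index_curve, annual_rate = 0.03)
round(convert_currency(c(insurer = cost$insurer, copay = cost$copay)))
#> insurer   copay
#>   46939    9940

validate_extrapolation(cohort, lt, fit_months = 60, test_months = 120,
                       seed = 3)$relative_bias
#> [1] -0.0038
```

That is: an expected lifetime insurer burden of about US$46,900 per
case plus US$9,940 patient copayments (3% discounting, KRW→USD at
1,131.2), and a 10-year restricted mean extrapolated from the first 5
years of data that is within 0.4% of the one observed with all 10
years — the split-sample check that justifies trusting the lifetime
extrapolation.

`run_all(pipeline_config(seed = 1))` chains every stage over the four
subtype scenarios (baseline table, LE/EYLL with bootstrap SEs,
costs at each discount rate, validation, CIR series) and writes a
reproducible bundle with a config manifest and hash.

The methods vignette (`vignettes/lifetime-outcomes.Rmd`) documents
the model, the excess-mortality gate, the stratification and window
choices, and the generator's scope.

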