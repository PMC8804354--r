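# pmpk

Population pharmacokinetics of an orally dosed kinase inhibitor (a ROS1/ALK
inhibitor developed for advanced solid tumours and ALK-positive anaplastic
large cell lymphoma) and its active metabolite, a crizotinib analog — with a
pediatric dose-extrapolation arm. The package is aimed at pharmacometricians
who want a self-contained, testable implementation of the whole workflow:
structural model, mixed-effects estimation, model qualification, and
simulation-based pediatric dose selection.

## The model

* **Parent drug**: one compartment, first-order absorption and elimination
  (`Ka`, `CL/F`, `V/F`). Typical adult estimates: `CL/F` = 2850 L/h,
  `V/F` = 4200 L, `Ka` = 51.9 1/h — a drug absorbed and cleared within
  hours (t½ ≈ 1.0 h).
* **Active metabolite**: two compartments (`Vcm/Fm` = 2300 L,
  `Vpm/Fm` = 1480 L, `Qm/Fm` = 113 L/h) fed by parent elimination
  (conversion fraction fixed to one on the molar scale), with
  **time-dependent clearance** from CYP3A4 auto-inhibition:

  ```
  CLm/Fm(t) = CLm0/Fm · [1 − TDPK · (1 − e^(−K_TDPK · t))]
  ```

  with `CLm0/Fm` = 126 L/h, maximum fractional reduction `TDPK` = 0.41 and
  rate `K_TDPK` = 0.0363 1/h. Steady-state metabolite half-lives: 4.9 h
  (distribution) and 39.4 h (elimination).
* **Statistics**: log-normal inter-individual variability on five
  parameters, proportional residual error per analyte, covariates as
  median-normalized power or fractional-change factors. Estimation is an
  FOCE-with-interaction-type Laplace approximation with M1/M3 handling of
  below-quantification-limit records, fitted sequentially (parent first,
  then the combined model with the parent stage fixed).
* **Pediatric arm**: allometric scaling (exponents 0.75/1, reference 59 kg)
  into a virtual 6–<18-year population, BSA-tiered BID dosing
  (`dose = BSA × 280 mg/m² × 1.09`, rounded to 50 mg), steady-state
  `Cmax,ss` / `AUC(0–12h),ss` of the metabolite matched to the reference
  pediatric exposure of crizotinib (GM 621 ng/mL and 6530 ng·h/mL).

No clinical data ship with the package; a synthetic-data module reproduces
the source study designs and covariate distributions so that every stage is
testable end to end. See the vignette
(`vignettes/parent-metabolite-poppk.Rmd`) for the methods account.

## Worked example

```r
library(pmpk)
p <- adult_reference_params()

parent_half_life(p$theta)
#> 1.02          # hours; rounds to the reported 1.0
metabolite_half_lives_ss(p$theta)
#> distribution  elimination
#>          4.9         39.4

# steady-state profiles on day 28 of 300 mg BID (ng/mL)
simulate_profile(p$theta, regimen_bid(300, 28), 648 + c(0, 1, 2, 4, 6, 12))
#>   time parent metabolite
#> 1  648    0.0      267.5
#> 2  649   36.7      316.3
#> 3  650   18.6      334.7
#> 4  652    4.8      333.2
#> 5  654    1.2      316.6
#> 6  660    0.0      267.5

# pediatric extrapolation under the recommended BSA tiers
vpop  <- generate_virtual_population(1000, seed = 1)
tiers <- recommended_tiers()
m <- simulate_exposure(vpop, tiers$dose[assign_tier(vpop$bsa, tiers)], p, seed = 2)
summarize_by_tier(m, tiers)[, c("tier", "dose", "n", "gm_cmax", "gm_auc")]
#>   tier dose   n gm_cmax gm_auc
#> 1    1  250 106   668.6 6847.4
#> 2    2  350 343   656.6 6854.6
#> 3    3  400 158   590.7 6203.4
#> 4    4  450 226   583.6 6249.6
#> 5    5  550 167   565.1 6100.7
```

The parent peaks and vanishes within each dosing interval while the
metabolite accumulates to a sustained plateau — the kinetic signature of
fast conversion plus slow metabolite elimination. The per-tier geometric
means sit within roughly ±7% of the crizotinib reference exposure
(621 ng/mL; 6530 ng·h/mL), which is the criterion the tier doses were
selected against.

A full synthetic study + sequential fit:

```r
ds <- generate_dataset(default_study_design(), p, seed = 42)  # 40 subjects
fit <- fit_sequential(ds, p, bql = "m3")
fit$combined$estimates
```

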