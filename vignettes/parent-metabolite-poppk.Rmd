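---
title: "Population PK of a parent-metabolite system with time-dependent clearance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK of a parent-metabolite system with time-dependent clearance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmpk)
```

# The model

`pmpk` models an orally dosed kinase inhibitor that is rapidly and almost
completely converted (N-deacetylation) to an active metabolite whose
structure and kinetics resemble crizotinib. The structural model is:

* **Parent**: one compartment with first-order absorption (`Ka`) and
  first-order elimination, apparent clearance `CL/F` and volume `V/F`. With
  `Ka` ~ 52 1/h and `CL/F` ~ 2850 L/h the parent peaks within the hour and
  is cleared with a half-life of about one hour.
* **Metabolite**: two compartments (`Vcm/Fm`, `Vpm/Fm`, inter-compartmental
  clearance `Qm/Fm`), fed by the parent elimination flux. Its apparent
  clearance declines with time on treatment,

  `CLm/Fm(t) = CLm0/Fm * (1 - TDPK * (1 - exp(-K_TDPK * t)))`,

  an exponential approach from the treatment-naive clearance `CLm0/Fm` to an
  asymptote `CLm0/Fm * (1 - TDPK)`. This mirrors the auto-inhibition of
  CYP3A4 by the metabolite under repeated dosing (the same phenomenon is
  documented for crizotinib). `t` is anchored at the subject's **first dose
  of the regimen**; the anchor is a documented modelling choice (the
  alternative, per-cycle resetting, is not supported by the source data,
  which dose continuously). With `K_TDPK` = 0.0363 1/h the decline is >99.99%
  complete well before day 28, so the final dosing interval of a 28-day
  schedule is used throughout as "steady state".

Because the conversion fraction cannot be identified from oral data alone,
it is fixed at one **on the molar scale**: every mole of parent eliminated
becomes a mole of metabolite. Amounts are tracked internally in parent-mass
equivalents and the metabolite mass concentration applies the nominal
molecular-weight ratio 449/491 (the true weights are proprietary; 491 minus
an acetyl group gives 449, consistent with the 1.09 parent/crizotinib dose
conversion used in the pediatric dosing rule). The same nominal weights
convert the assay's molar quantification limit (1 nmol/L for both analytes)
to the mass-unit LLOQs 0.491 and 0.449 ng/mL. We verified this convention
against the published steady-state exposures it has to reproduce: the
per-tier pediatric geometric-mean AUCs are consistent with
`AUC = (449/491) * dose / CLm_ss` and inconsistent with a mass-equivalent
(1 mg to 1 mg) bookkeeping, and the published goodness-of-fit diagnostics
are stated in molar concentration units.

Units elsewhere: doses mg, times h, concentrations ng/mL.

## Numerical scheme

The depot and parent compartments are linear with constant coefficients and
are propagated **analytically** between events (the degenerate `ka = ke`
Bateman case uses its analytic limit, not a perturbation). Only the two
metabolite states are integrated numerically — adaptive Dormand-Prince
RK4(5) with step-size memory across dose intervals, default tolerances
`rtol 1e-8`, `atol 1e-10`, integration restarts at every dose event so event
times are exact. Mass balance (all compartments plus cumulative metabolite
elimination versus total administered dose) closes to 1e-6, and the parent
channel agrees with Bateman superposition to solver tolerance; the test
suite cross-checks the full four-state system against an independent
`deSolve::lsoda` integration.

```{r}
p <- adult_reference_params()$theta
parent_half_life(p)
metabolite_half_lives_ss(p)   # 2-compartment macro constants at CL_ss
```

# The stochastic model and estimation

Inter-individual variability is log-normal (`theta_i = theta_tv * e^eta`),
with independent etas on `CL/F`, `V/F`, `CLm0/Fm`, `Vcm/Fm` and `Vpm/Fm`
only; a reported %CV is interpreted as 100 times the SD of eta (the usual
convention at these magnitudes). Residual error is proportional per analyte,
`y = f(1 + eps)` (additive and combined forms exist as options). Covariates
enter multiplicatively: power functions normalized to the population median
for continuous covariates, fractional-change factors for categorical ones.

`fit_pk()` maximizes an approximate marginal likelihood of the FOCE-I
family: per subject, the random effects are optimized to their conditional
mode (damped Newton with a Gauss-Newton Hessian, prediction Jacobians by
forward differences, one extra integration per eta dimension), and the
Laplace correction `log det(H/2)` uses the observed curvature of the
conditional objective at the mode, with the residual variance evaluated at
the conditional prediction (interaction). The tests hold this approximation
to within 0.5 objective units of an adaptive Gauss-Hermite quadrature of the
exact marginal likelihood on toy subjects across a grid of omega and sigma;
observed agreement is about 0.25 in the worst corner.

Numerical safeguards, each of which was needed in practice: predictions are
floored at 1e-10 ng/mL inside the proportional-error variance; Newton steps
over eta are capped at length 2 so that backtracking explores useful scales
even when a far-tail observation makes the gradient astronomically large;
etas are clamped to ±7 (e^7-fold, far beyond plausibility) to keep trial
points out of numerically hostile integration regimes; the warm-started
conditional modes are only a hint — if a warm start ends worse than the
prior mode, the subject is re-solved from eta = 0, so results do not depend
materially on optimization history. The outer problem is solved by a
quasi-Newton method on transformed scales (log for positive parameters and
the omega/sigma SDs, logit for `TDPK`), with an explicit central-difference
gradient evaluated without updating the warm state, box bounds 4 log-units
around the initial estimates, and convergence declared when a restart no
longer improves the objective by more than 0.1 units (a relative-objective
criterion; estimation-time integration tolerance is relaxed to 1e-6/1e-9,
far below the statistical resolution of the objective).

Censored observations can be discarded (M1) or contribute
`-2 log Phi((LLOQ - f)/(sigma f))` (M3). **A consequence worth
understanding**: under the generating model, proportional error with
`sigma_p = 0.711` places about 8% of parent draws below zero, hence below
any positive LLOQ. Discarding them (M1) conditions on an upper tail and
biases the parent fit (about -15% on CL/F in our experiments), while M3 is
the matching, consistent likelihood; the recovery experiments therefore use
M3 for the parent stage. M1 remains the package default for data analysis,
mirroring the source analysis (where M3 did not converge in the original
software), and the metabolite stage keeps M1 (sigma_m = 0.319 leaves the
truncation effect negligible at its ~6% BQL rate).

Fitting is **sequential**: stage 1 fits the parent alone; stage 2 fixes the
parent fixed effects, IIV and residual SD at their stage-1 estimates
(fixing both is the deterministic reading of "parameter estimates ...
fixed") and estimates the metabolite structure, with parent and metabolite
etas re-evaluated jointly at their conditional modes. Stepwise covariate
search uses forward inclusion at dOFV > 3.8 and backward elimination at
dOFV > 6.6, the thresholds taken literally.

# Synthetic study data

No clinical data ship with the package. `generate_dataset()` emulates the
two source studies: single doses of 100/200 mg sampled to 168 h;
100/200/300 mg QD for 28 days; 200/250/300/350 mg BID for 28 days, each with
rich day-1/day-28 sampling and pre-dose troughs on days 7/14/21. Forty
subjects (34 adults, 6 adolescents, the adolescents confined to the BID
arms) are split evenly across arms within each study — the true per-arm
allocation was not published, so the split is a declared default, not an
inference. Baseline covariates are drawn per stratum from log-normal/normal
distributions matched to the published summary statistics and truncated to
the published ranges (log-normal shapes chosen for positivity; serum
creatinine was not tabulated and uses a plausible synthetic spec).
Concentrations receive proportional residual error and are censored at the
molar-derived LLOQs, keeping censored rows flagged `BLQ = 1`. Under the
default design the censoring pattern reproduces the source data's
qualitative signature (roughly half of parent samples below the limit
versus ~6% for the metabolite).

What passing recovery tests do **not** show: real assay error is not
exactly normal-proportional, real subjects miss visits, and the true
per-arm allocation is unknown, so recovery on this generator demonstrates
estimator correctness under the assumed mechanism, not robustness to
real-data pathologies.

# Pediatric extrapolation

The extrapolation arm scales the adult typical parameters to a virtual
6-<18-year population by fixed-exponent allometry (0.75 on clearances, 1 on
volumes, reference 59 kg = the adult median body weight; the pooled median
58.3 kg is available as an option). CYP3A4/5 activity matures years before
age 6, so body size is taken as the only systematic difference.

`generate_virtual_population()` draws age uniformly on [6, 18), sex with
male fraction 0.541, and anthropometry from a packaged **synthetic** growth
reference (`extdata/growth_reference_synthetic_asian.tsv`): sex-specific
median height-for-age and BMI-for-age, constructed to emulate the Asian
(Japanese-survey-based) reference population behind the published virtual
cohort, with log-normal variation (SD 0.04 for height, 0.14 for BMI) tuned
once so that an n = 1000 draw lands on the published cohort medians (age
~12, weight ~42 kg, BMI ~18.4, BSA ~1.3 m^2). The true database is
proprietary; agreement is calibration-level, not exact. BSA uses Mosteller
by default (the source never names its formula; Du Bois is available).

Dosing follows the label-derived rule `dose = BSA x 280 mg/m^2 x 1.09`,
rounded to the nearest 50 mg (ties up; all published tier doses are 50-mg
multiples), with BSA values sharing a rounded dose lumped into tiers.
Steady-state exposure is simulated per subject over 28 days BID with IIV
included and **no residual error** in the metrics — the published per-tier
CVs (~27-31% for AUC) match eta-level plus body-size variability and would
be inflated markedly by the 31.9% assay-error term. `Cmax,ss` is the
maximum on the published sampling grid (0, 0.5, 1, 2, 4, 6, 10, 12 h after
the final-day morning dose) and `AUC(0-12h),ss` the linear trapezoid on that
grid. Tier-dose optimization targets the geometric-mean AUC against the
reference exposure (6530 ng*h/mL; Cmax 621 ng/mL is reported but not
targeted — the source does not state its objective), searching the 50-mg
grid with ties to the lower dose; kinetics are dose-linear, so per-subject
exposure is simulated once and scaled exactly along the dose grid.

A known, deliberate limitation: with an honestly constructed growth
reference, the 0.90-1.22 m^2 / 350 mg tier simulates ~9-13% above the
reference geometric-mean exposure while all other tiers fall within ~2-6%.
The published per-tier values imply a heavier weight-for-BSA in
mid-childhood than any standard growth reference produces; reproducing that
would require the proprietary population itself, and we chose not to distort
the generator to force agreement.

```{r, eval = FALSE}
vpop <- generate_virtual_population(1000, seed = 1)
tiers <- recommended_tiers()
metrics <- simulate_exposure(vpop, tiers$dose[assign_tier(vpop$bsa, tiers)],
                             adult_reference_params(), seed = 2)
summarize_by_tier(metrics, tiers)
```

# Diagnostics

`bootstrap_fit()` resamples subjects with replacement (refitting from the
original initial values, the common pharmacometric practice) and summarizes
converged replicates by median and 2.5/97.5 percentiles. `pc_vpc()`
implements the prediction-corrected visual predictive check: binning by
nominal time after dose (the design's nominal times by default, sparse bins
merged leftward), correction by the binwise median population prediction,
simulated 95% bands for the 2.5th/50th/97.5th percentiles (500 replicates
by default; both observed and simulated values below the LLOQ are excluded,
a documented simplification). `gof_table()` returns population and
conditional-mode individual predictions with `IWRES = (DV - IPRED) /
(sigma * IPRED)`, censored records excluded.

# Problem sizes used by the shipped checks

The packaged experiments are sized for a single CPU: parameter recovery
uses 9 replicate synthetic 40-subject trials (medians across replicates are
what the recovery claims are about, and 9 gives a usefully stable median);
the pediatric simulation uses the full n = 1000 cohort; bootstrap and VPC
calibration checks run on 12-16-subject subsets of the design with 30-150
replicates. Each sequential fit takes seconds to ~1 minute depending on how
flat the replicate's TDPK/K_TDPK/CLm0 ridge is.

# Known limitations

* The estimator is a Laplace/FOCE-I approximation; like all such methods it
  can show mild omega shrinkage-bias at small n.
* The `TDPK`-`K_TDPK`-`CLm0/Fm` triplet is weakly identified in occasional
  replicates (a flat likelihood ridge); medians across replicates are the
  meaningful recovery summary.
* The virtual pediatric population is a synthetic emulation; per-tier
  exposures inherit its anthropometry (see above).
* No inter-occasion variability, no off-diagonal omega, no M2/M4 censoring
  methods, no enterohepatic recirculation or Michaelis-Menten elimination
  (an MM form of the clearance decline was considered and rejected in the
  source analysis; only the exponential form is implemented).
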