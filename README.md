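# dmchain

Aging-chain simulation of diabetes prevalence and of dialysis due to
diabetic nephropathy, with weighted least-squares calibration and
intervention scenario analysis.

## The problem

Japan combines a slowly shrinking adult population with rising diabetes
prevalence and one of the highest dialysis rates in the world; diabetic
nephropathy is the leading cause of dialysis initiation. Health-policy
planners need projections of two linked quantities — the number of adults
with diabetes and the number on dialysis due to diabetic nephropathy — and
a way to compare interventions that act at different points of the disease
pathway: preventing diabetes itself (lifestyle programmes) versus
preventing progression to end-stage renal disease in people who already
have diabetes (glycaemic and blood-pressure control).

`dmchain` implements a system-dynamics answer for epidemiologists and
health-services researchers: a sex-specific stock-and-flow **aging chain**
over six age bands (20–29, 30–39, 40–49, 50–59, 60–69, 70+) and three
health states — no diabetes (`NDM`), diabetes not on dialysis (`DM`), and
on dialysis due to diabetic nephropathy (`DMDi`, ages 40+ only). The
package covers the full pipeline: turning published statistics into the
observation cross-table, calibrating the unknown transition rates,
projecting under intervention scenarios, and sensitivity analysis, plus a
synthetic-data generator so every estimation step can be verified by
parameter recovery against known truth.

## The model

Per sex, 16 stocks `X[s,a]` (state `s`, band `a`) evolve in continuous
time. With entry cohort `E(t)` (persons/yr reaching age 20), entry
diabetes prevalence `p0 = 0.002`, exogenous mortality rates
`mu[s,a](t)`, dialysis inflow at age 40 `D40(t)`, and calibrated constant
rates `ir_dm[a]` (diabetes incidence, NDM→DM) and `ir_di[a]` (dialysis
initiation, DM→DMDi, bands 40+):

```
d NDM[a]/dt = aging_in − NDM[a]/10 − ir_dm[a]·NDM[a] − mu[NDM,a]·NDM[a]   (+ E·(1−p0) into band 20–29)
d DM[a]/dt  = aging_in − DM[a]/10 + ir_dm[a]·NDM[a] − ir_di[a]·DM[a] − mu[DM,a]·DM[a]   (+ E·p0)
d DMDi[a]/dt = aging_in − DMDi[a]/10 + ir_di[a]·DM[a] − mu[DMDi,a]·DMDi[a]   (+ D40 into band 40–49)
```

Each closed 10-year band ages out at `stock/10` per year; the open 70+
band is terminal. Dialysis patients under 40 are outside the model; they
enter as the exogenous inflow `D40`. All-cause mortality is decomposed
into non-diabetic and diabetic rates assuming diabetics die at twice the
non-diabetic rate, and dialysis deaths are stripped out of the diabetic
rate by death-count bookkeeping.

Calibration minimises the weighted squared error between simulated and
observed stocks (population, diabetics, dialysis patients per band,
2000–2015), each series weighted by the inverse of its window mean, using
bounded Levenberg–Marquardt with deterministic multi-start.

Interventions are multiplier ramps on a rate family: from 1 in 2015
linearly down to 0.5 in 2025, flat thereafter. `DMP` ramps diabetes
incidence, `ESRDP` ramps dialysis initiation (and the age-40 inflow),
`DMP+ESRDP` ramps both.

## Worked example

```r
library(dmchain)
fix <- build_japan_like_fixture()   # anchor-built observation table
fix
#> male: 2000-2015 | pop20+ 47.3M -> 47.5M | DM 4.19M -> 5.32M | dialysis 34,672 -> 83,858
#> female: 2000-2015 | pop20+ 49.9M -> 50.9M | DM 2.90M -> 3.39M | dialysis 17,219 -> 35,048

fit <- dmchain(fix, "male")          # calibrate the 10 male rates
fit
#> Calibrated aging-chain model (male)
#>   window: 2000-2015; payoff = 1.017
#>     DM2029ir     DM3039ir     DM4049ir     DM5059ir     DM6069ir   DMover70ir
#>    0.0008666    0.0022640    0.0048860    0.0130400    0.0171900    0.0000000
#>   DMDi4049ir   DMDi5059ir   DMDi6069ir DMDiover70ir
#>    0.0008949    0.0020650    0.0028830    0.0019430

base <- predict(fit, horizon = 2035)
cmp <- rbind(compare_runs(base, predict(fit, scenario = "DMP"),   2035),
             compare_runs(base, predict(fit, scenario = "ESRDP"), 2035))
cmp[, c("scenario", "variable", "base_level", "scenario_level", "pct_reduction")]
#>   scenario   variable base_level scenario_level pct_reduction
#> 1      DMP    TotalDM    5868883        4504471       23.2482
#> 2      DMP DMDiover40     115500         100201       13.2458
#> 3    ESRDP    TotalDM    5868883        5885778       -0.2879
#> 4    ESRDP DMDiover40     115500          68779       40.4507
```

Reading the output: the calibrated diabetes-incidence hazards rise from
~0.09%/yr in the 20s to ~1.7%/yr in the 60s, and dialysis-initiation
hazards sit around 0.1–0.3%/yr — plausible Japanese magnitudes. The base
run projects 115,500 males on dialysis due to diabetic nephropathy in
2035. Halving diabetes incidence by 2025 (`DMP`) cuts the 2035 diabetic
population by 23% but the dialysis population by only 13% — prevention
reaches the dialysis queue with a decade-plus delay — while halving
dialysis initiation (`ESRDP`) cuts the dialysis population by 40% and
leaves the diabetic population essentially unchanged (a small negative
"reduction": avoided initiations keep people in the `DM` stocks).

`run_full_pipeline(dmchain_config(out_dir = "out"))` runs everything —
data, per-sex calibration, all scenarios, comparison table — and writes
tidy CSVs. The synthetic-data loop for verifying the estimator is
`default_truth()` → `generate_synthetic_country()` → `dmchain()` →
compare `coef()` with the truth.

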