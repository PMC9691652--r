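---
title: "Model and methods: MitraClip vs medical therapy in a Chinese setting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitracea)
```

## The decision problem

Severe secondary mitral regurgitation in heart failure can be treated with
transcatheter edge-to-edge repair (MitraClip) on top of optimal medical
therapy (OMT), or with OMT alone. The device is expensive; whether the
survival and quality-of-life gains justify its cost depends on the payer's
willingness to pay (WTP) per quality-adjusted life-year. This package
implements that comparison for a Chinese healthcare-payer perspective with
a WTP of three times 2021 per-capita GDP (3 × 80,976 = 242,928 CNY/QALY).

## Model structure

The model has two stages.

**30-day decision tree.** Patients are allocated to an arm. The MitraClip
arm is charged the eight one-time procedure-related cost components
(device, procedure, diagnosis, medicine, complications, ward, nursing,
others; 395,659 CNY in total) plus one month of OMT, and incurs one-time
disutilities for the procedure (0.043) and averaged complications (0.005).
The OMT arm is charged one month of OMT. Each arm leaves the stage with a
per-arm NYHA distribution; an optional per-arm 30-day mortality (default
0) moves the corresponding mass to the death state. One-time stage
quantities enter undiscounted at time zero — a choice forced by the
scenario arithmetic: lifetime-cost differences across device prices equal
the price differences exactly only if the device cost is never discounted.
Whether the first month of OMT cost belongs to the stage or to the first
Markov cycle is not externally fixed; charging it in the stage and
starting Markov accrual at cycle 1 is the convention used here (the
alternative shifts totals by under one month of OMT cost).

**Markov cohort model.** Five states: NYHA I–IV and absorbing death, fed
only by heart-failure death out of NYHA III/IV (no background all-cause
mortality — the short life expectancies produced by the transition matrix
alone are consistent with the severity of this population). Monthly
cycles, time-homogeneous per-arm 5×5 transition matrices, horizon 336
cycles (age 72 to 100, far beyond the cohort's life expectancy). Zeros in
the matrices are structural: NYHA IV patients cannot improve, NYHA I
patients cannot die of heart failure directly; no analysis ever perturbs
them.

## Accrual conventions

Let $x_t$ be the occupancy row-vector after $t$ cycles ($x_0$ is the
post-stage distribution). Per-cycle quantities use an *effective*
occupancy:

- with half-cycle correction (the default): $\tfrac12(x_{t-1} + x_t)$,
  the trapezoidal average of start- and end-of-cycle occupancy;
- without: $x_t$, the end-of-cycle occupancy.

One convention is applied engine-wide — to life-years, expected
hospitalizations, costs and QALYs alike — and the microsimulation uses the
end-of-cycle convention by construction (a simulated patient accrues a
cycle's flows only if alive after that cycle's transition). This keeps the
cohort engine exactly the expectation of the microsimulation when the
correction is disabled. For a single transient state with monthly death
probability $p$, expected survival is $(1-p)/p$ months end-of-cycle and
$(1-p)/p + \tfrac12$ with correction; the test suite checks both closed
forms and the two-cycle enumeration of expected cost.

Monthly cost flows are OMT cost plus the hospitalization probability of
the occupied state times the per-event cost; monthly utility is the
state's monthly utility (annual utility / 12) minus the event probability
times the per-event disutility. Disutilities are stored as positive
magnitudes and subtracted, avoiding double-negation ambiguity. Both costs
and QALYs are discounted with the monthly factor $(1+r)^{1/12}-1$ derived
from the single annual rate $r$ (default 0.05, varied 0–0.08 in
sensitivity analysis); $r/12$ simple division is deliberately not used.

## Parameters

All inputs live in one configuration document
(`cea_base_case()` returns the bundled YAML). Key entries, with units:

- **Costs (CNY)**: one-time MitraClip components; OMT 428/month;
  hospitalization 10,926/event. The latter two are derived quantities —
  subgroup-weighted means in source-era USD, converted at 6.75 CNY/USD,
  inflated through the 2018–2021 healthcare CPI chain
  (1.043, 1.024, 1.018, 1.004), and (for OMT) divided by 12. The package
  re-derives them from the raw figures in its tests; USD reporting uses
  the separate 2021 average rate of 6.45 CNY/USD.
- **Utilities (per month)**: NYHA I 0.065, II 0.065 (equal by source, kept
  as printed), III 0.060, IV 0.055; death 0. Validation enforces
  monotonicity in severity and the 1/12 monthly ceiling.
- **Transitions (per month)**: per-arm 5×5 matrices; rows must sum to 1
  within 1e-12.
- **Economics**: discount rate 0.05/year; per-capita GDP 80,976 CNY; WTP
  derived as 3 × GDP when not set explicitly.

### Uncertainty distributions

Each uncertain parameter carries a 95% interval interpreted symmetrically:
$\sigma = (\text{high}-\text{low})/(2\times1.96)$, even where the printed
interval is asymmetric (half-to-double ranges around most costs) — the
interval is *named* a confidence interval by its source, not a
parameterization, so moment matching on $\sigma$ is the least-committal
reading. Costs use gamma ($\text{shape}=\mu^2/\sigma^2$,
$\text{rate}=\mu/\sigma^2$); utilities, disutilities and transition
probabilities use beta (method of moments). Whether the interval is an
exact CI or only a deterministic-sensitivity plausibility band is not
stated by the source; both uses here share the same bounds. Transition
probabilities carry no printed intervals at all, so every structurally
nonzero off-diagonal entry is given a beta distribution with a 95% CI of
±25% of its base value (`transition_uncertainty.ci_halfwidth_fraction`,
adjustable). The degenerate case low = high collapses to a point mass and
is excluded from probabilistic draws.

## Calibration of unreported parameters

Two parameter blocks of the original evaluation are unpublished: the
post-30-day NYHA distribution per arm, and the per-state monthly
hospitalization probabilities per arm. They are exposed as ordinary
configuration entries, and `calibrate_parameters()` fits them to reported
outcomes by bounded least squares on the sum of squared relative errors.

Two structural facts make this fast and well-behaved. The cohort trace is
linear in the entry distribution, and all accruals are linear in both the
entry distribution and the hospitalization risks; every target is
therefore a bilinear form in the free parameters, and per-start-state
occupancy summaries computed once reduce an objective evaluation to a few
dot products. Optimization runs on unconstrained transforms — softmax for
the simplex, logit for single probabilities, and an ordered-logit
(cumulative-softplus) transform for whole-arm hospitalization blocks,
which encodes the clinical expectation that hospitalization risk does not
decrease with NYHA severity. Multi-start BFGS (first start = current
values, further starts randomized from a seed) guards against local
minima.

The shipped configuration contains the result of fitting both blocks to
the eight published lifetime outcomes (per-arm life-years 3.72/2.90,
hospitalizations 1.16/1.51, QALYs 2.32/1.80, costs 423,817/28,369 CNY);
the archived fit report is at `inst/extdata/calibration_report.json`, and
every target — and the implied ICER of 754,410 CNY/QALY — is reproduced
within 2%. The fitted MitraClip entry mix concentrates in NYHA II
(~96%), consistent with the marked 30-day functional improvement after
the procedure, while the OMT mix stays near the trial's baseline II/III
split. The fitted values are stand-ins, not estimates of the unpublished
sources: with more free parameters than targets the fit is not unique,
and the ordering constraint plus warm-started optimization select one
clinically plausible representative.

## Sensitivity analyses

**One-way (tornado).** Each parameter in turn is set to its interval
bounds with everything else at base, and the full deterministic pipeline
is re-run; entries are ranked by ICER swing. With the shipped inputs the
device cost dominates, followed by the discount rate.

**Probabilistic.** 10,000 draws by default. Each drawn parameter uses its
own RNG substream derived deterministically from the master seed and the
parameter's name, so adding or removing a parameter never shifts the
others' draws and any single stream can be reproduced in isolation. After
drawing the nonzero off-diagonal transition entries of a row
(marginally — the joint row distribution is unpublished, so marginal beta
with re-balancing is the convention chosen here), the same-state diagonal
entry absorbs the difference; in the rare case the off-diagonal mass
exceeds 1 the row is rescaled and the diagonal set to 0. Structural zeros
are never drawn. The acceptability curve evaluates the fraction of draws
with positive net monetary benefit on a WTP grid of 0 to 1.5 million
CNY/QALY in 10,000-CNY steps, wide enough to contain the acceptability
crossover near 750,000 CNY/QALY.

## The synthetic oracle

`simulate_patients()` is an individual-level Monte Carlo simulator sharing
no propagation code with the cohort engine: patients draw an entry state,
step through the transition matrix, and realize Bernoulli hospitalization
events independently of transitions (the same independence the cohort
engine assumes). It deliberately omits half-cycle correction, so
cohort-vs-microsimulation comparisons are run with the correction
disabled, isolating the correction as a separately tested term.
`generate_fixture()` emits valid configuration documents — the exact base
case at `jitter = 0`, or invariant-preserving perturbations within the
declared intervals otherwise — so every stage is testable without any
external data.

What the generator emulates: parameter sets of the declared shape and
uncertainty ranges, and cohorts homogeneous in everything but NYHA state.
What it does not: patient-level covariates (age, sex, ventricular
geometry), time-varying transition risks, competing non-cardiac mortality,
or correlation between parameters. Passing tests therefore demonstrate
internal consistency of the engines and arithmetic, not external validity
of the published inputs.

## Numerical choices and degenerate inputs

- Row-stochasticity and simplex checks use 1e-12; trace mass conservation
  is asserted to 1e-9 over 336 cycles.
- ICER is reported `NA` (not infinite) at zero incremental effectiveness;
  a strictly dominant intervention is labelled `"dominant"` rather than
  given a negative ratio.
- The threshold device price uses the closed form
  $d^* = d_0 - \Delta C + \lambda \, \Delta E$ from cost affinity; its
  fixed-point property (re-running the scenario at $d^*$ returns an ICER
  equal to $\lambda$ within 1e-6 relative) is tested. A negative $d^*$ is
  returned with a warning — no non-negative price reaches the threshold.
- Calibration transforms clamp probabilities to [1e-6, 1−1e-6] before
  inversion; optimizer failures raise an error rather than silently
  returning the start.

## Validation problem sizes

The test suite compares the cohort engine against the microsimulation at
n = 100,000–200,000 patients (3 Monte Carlo standard errors), checks
empirical transition frequencies over more than 10^6 simulated
transitions, verifies distribution means on 10^5 draws per parameter, and
exercises ten jittered configurations end-to-end. The bundled acceptance
script re-runs the deterministic arithmetic, the calibrated base case and
a 10,000-draw PSA.

## Known limitations

- No background (non-cardiac) mortality and no age-dependence in the
  transition matrices; the model is not suitable for horizons where
  competing mortality matters.
- Hospitalization risk is a per-state constant, independent of history;
  repeat-admission clustering is not modelled.
- The calibrated stand-in parameters reproduce published aggregate
  outcomes but are not identified by them; conclusions that depend on the
  *composition* of the entry mix or per-state risks (rather than the
  aggregate outputs) should not be drawn from the defaults.
- Two-strategy comparison only; no EVPI or multi-comparator CEAC frontier.
- Healthcare-payer perspective: no societal or productivity costs.
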