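# mitracea

Cost-effectiveness modelling of transcatheter edge-to-edge mitral-valve
repair (MitraClip) versus optimal medical therapy (OMT) in heart-failure
patients with secondary mitral regurgitation, from a Chinese
healthcare-payer perspective.

## Who this is for

Health economists and HTA analysts who want a fully scripted, testable
version of a decision-tree + Markov cohort evaluation: every input lives in
a plain YAML/JSON configuration, every stage (parameter derivation, cohort
propagation, discounted accrual, scenario and sensitivity analysis) is an R
function returning a tibble, and an individual-level microsimulation is
bundled as an independent cross-check of the cohort engine.

## The model

A 30-day decision tree assigns a hypothetical cohort (entry age 72) to
MitraClip + OMT or OMT alone. The MitraClip arm is charged eight one-time
procedure-related cost components (395,659 CNY in total, of which the
device is 322,000 CNY) and one-time procedure/complication disutilities;
both arms then enter a Markov model over the live states NYHA I–IV plus an
absorbing death state, with monthly cycles to age 100 (336 cycles) and
half-cycle correction. Each month, patients accrue OMT cost, NYHA-state
utility, and a state-dependent probability of heart-failure
hospitalization (one-time cost 10,926 CNY and disutility 0.10 per event).
Costs and QALYs are discounted at 5%/year, compounded monthly.

For strategies *i* (intervention) and *c* (comparator):

- ICER = (C_i − C_c) / (E_i − E_c), in CNY per QALY
- NMB(λ) = λ·ΔE − ΔC, with willingness-to-pay λ = 3 × per-capita GDP
  = 242,928 CNY/QALY

Because the device cost enters undiscounted at time zero, lifetime cost is
affine in the device price; scenario analyses over regional device prices
and the closed-form cost-effective ("threshold") price follow from that.
One-way sensitivity varies each parameter across its 95% interval; the
probabilistic sensitivity analysis draws costs from moment-matched gamma
distributions and utilities/transition probabilities from beta
distributions (10,000 Monte Carlo iterations) and summarizes the draws as
a scatter plot and cost-effectiveness acceptability curve.

Two inputs of the underlying evaluation are not published: the NYHA mix at
the end of the 30-day stage and the per-state monthly hospitalization
risks. The package treats them as first-class configuration entries and
ships values fitted by `calibrate_parameters()` to the published lifetime
outcomes; they are flagged as calibrated stand-ins in the configuration
file and can be overridden or refitted.

## Worked example

```r
library(mitracea)

params <- load_parameters(cea_base_case())
res <- run_cea(params)
res
#> <cea_result> MitraClip vs optimal medical therapy
#>
#> # A tibble: 2 × 6
#>   arm       lifetime_cost lifetime_qaly life_years hospitalizations
#>   <chr>             <dbl>         <dbl>      <dbl>            <dbl>
#> 1 mitraclip       423455.          2.30       3.75             1.16
#> 2 omt              28222.          1.78       2.94             1.51
#> # ℹ 1 more variable: undiscounted_cost <dbl>
#>
#> # A tibble: 1 × 7
#>   delta_cost delta_qaly    icer dominance      nmb icer_wtp_ratio    wtp
#>        <dbl>      <dbl>   <dbl> <chr>        <dbl>          <dbl>  <dbl>
#> 1    395232.      0.522 757682. none      -268513.           3.12 242928
```

MitraClip gains about 0.52 QALY at an extra lifetime cost of ~395,000 CNY;
the ICER of ~758,000 CNY/QALY is about 3.1 times the willingness-to-pay
threshold, so MitraClip is not cost-effective at current Chinese prices.
The device price at which it would become cost-effective:

```r
threshold_device_price(res, params)
#> [1] 53487.08
#> attr(,"overall_onetime")
#> [1] 127146.1
```

Scenario analysis at regional device prices, PSA and the acceptability
curve:

```r
scenario_table(res, params)        # Germany / USA / Japan / UK prices
psa <- run_psa(params, n_iter = 10000, seed = 1)
glance(psa)                        # acceptability ~0.1% at the threshold
autoplot(ceac(psa))                # crossover near 750,000 CNY/QALY
tor <- one_way_sensitivity(params) # device cost dominates the tornado
autoplot(tor)
```

Every result type has `tidy()`/`glance()` and `autoplot()` methods. A thin
command-line front end ships in `inst/cli/mitracea`
(`run`, `scenario`, `dsa`, `psa`, `calibrate` subcommands).

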