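# Base-case configuration: MitraClip + OMT vs OMT alone, Chinese
# healthcare-payer perspective, monthly-cycle NYHA Markov model.
#
# Cost/utility/transition inputs and economic settings are published values.
# The post-30-day NYHA distributions and per-state monthly HF-hospitalization
# risks are NOT published; the values below are calibrated stand-ins fitted
# by mitracea::calibrate_parameters() to the published lifetime outcomes
# (life-years 3.72/2.90, hospitalizations 1.16/1.51, QALYs 2.32/1.80).
# See inst/extdata/calibration_report.json for the archived fit report.

costs:
  mitraclip_onetime:        # CNY, charged once at procedure time
    device: 322000
    procedure: 12172
    diagnosis: 16249
    medicine: 5018
    complications: 15070
    ward: 683
    nursing: 659
    others: 23808
  omt_monthly: 428          # CNY per month, both arms
  hf_hospitalization: 10926 # CNY per event

scenario_device_costs:      # CNY, device prices in other regions
  germany: 247478
  usa: 197597
  japan: 179504
  uk: 143951

utilities:
  monthly:                  # utility per month by NYHA class (annual / 12)
    nyha1: 0.065
    nyha2: 0.065
    nyha3: 0.060
    nyha4: 0.055
  disutility:               # stored as positive magnitudes, subtracted once
    complications: 0.005    # averaged one-time complication disutility
    procedure: 0.043        # one-month procedure disutility
    hf_hospitalization: 0.10 # per hospitalization event

transitions:                # monthly probabilities, rows sum to 1
  mitraclip:
    nyha1: {nyha1: 0.960, nyha2: 0.040, nyha3: 0.0, nyha4: 0.0, dead: 0.0}
    nyha2: {nyha1: 0.005, nyha2: 0.945, nyha3: 0.050, nyha4: 0.0, dead: 0.0}
    nyha3: {nyha1: 0.0, nyha2: 0.025, nyha3: 0.895, nyha4: 0.070, dead: 0.010}
    nyha4: {nyha1: 0.0, nyha2: 0.0, nyha3: 0.0, nyha4: 0.800, dead: 0.200}
  omt:
    nyha1: {nyha1: 0.950, nyha2: 0.050, nyha3: 0.0, nyha4: 0.0, dead: 0.0}
    nyha2: {nyha1: 0.010, nyha2: 0.940, nyha3: 0.040, nyha4: 0.010, dead: 0.0}
    nyha3: {nyha1: 0.0, nyha2: 0.020, nyha3: 0.920, nyha4: 0.050, dead: 0.010}
    nyha4: {nyha1: 0.0, nyha2: 0.0, nyha3: 0.0, nyha4: 0.750, dead: 0.250}

hospitalization_risk:       # monthly Pr(HF hospitalization) by NYHA class
  mitraclip:                # CALIBRATED (see header note)
    nyha1: 0.0028834058
    nyha2: 0.0030154801
    nyha3: 0.0030465714
    nyha4: 0.2370681282
  omt:                      # CALIBRATED
    nyha1: 0.0002489838
    nyha2: 0.0008369658
    nyha3: 0.0858193392
    nyha4: 0.0899882418

decision_tree:
  initial_distribution:     # NYHA mix on leaving the 30-day stage
    mitraclip:              # CALIBRATED
      nyha1: 0.0000348488
      nyha2: 0.9619626450
      nyha3: 0.0380022996
      nyha4: 0.0000002066
    omt:                    # CALIBRATED
      nyha1: 0.0002316786
      nyha2: 0.4770451505
      nyha3: 0.5227229168
      nyha4: 0.0000002541
  thirty_day_mortality:     # no death branch in the 30-day stage
    mitraclip: 0.0
    omt: 0.0

economics:
  annual_discount_rate: 0.05
  per_capita_gdp: 80976     # CNY, 2021
  wtp_threshold: ~          # null -> derived as 3 x per-capita GDP = 242,928
  reporting_exchange_rate: 6.45  # CNY/USD, 2021 average, for USD reporting
  source_exchange_rate: 6.75     # CNY/USD, used in source-era cost derivations
  cpi_factors: [1.027, 1.038, 1.060, 1.043, 1.024, 1.018, 1.004]  # 2015-2021 healthcare CPI

model:
  entry_age: 72
  terminal_age: 100         # 336 monthly cycles
  cycle_length_months: 1
  half_cycle_correction: true

transition_uncertainty:
  ci_halfwidth_fraction: 0.25  # 95% CI = base +/- 25% for nonzero off-diagonals

uncertainty:                # 95% intervals; gamma for costs, beta for [0,1]
  cost_device: {family: gamma, base: 322000, low: 161000, high: 386400}
  cost_procedure: {family: gamma, base: 12172, low: 6086, high: 24343}
  cost_diagnosis: {family: gamma, base: 16249, low: 8125, high: 32499}
  cost_medicine: {family: gamma, base: 5018, low: 2509, high: 10037}
  cost_complications: {family: gamma, base: 15070, low: 7535, high: 30140}
  cost_ward: {family: gamma, base: 683, low: 341, high: 1365}
  cost_nursing: {family: gamma, base: 659, low: 330, high: 1319}
  cost_others: {family: gamma, base: 23808, low: 11904, high: 47616}
  cost_omt_monthly: {family: gamma, base: 428, low: 214, high: 856}
  cost_hf_hospitalization: {family: gamma, base: 10926, low: 5463, high: 21852}
  utility_nyha1: {family: beta, base: 0.065, low: 0.062, high: 0.068}
  utility_nyha2: {family: beta, base: 0.065, low: 0.062, high: 0.068}
  utility_nyha3: {family: beta, base: 0.060, low: 0.057, high: 0.063}
  utility_nyha4: {family: beta, base: 0.055, low: 0.052, high: 0.058}
  disutility_complications: {family: beta, base: 0.005, low: 0.003, high: 0.007}
  disutility_procedure: {family: beta, base: 0.043, low: 0.034, high: 0.051}
  disutility_hf_hospitalization: {family: beta, base: 0.10, low: 0.08, high: 0.13}
  discount_rate: {family: fixed, base: 0.05, low: 0.0, high: 0.08}
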