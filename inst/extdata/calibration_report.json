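{
  "targets": {
    "life_years_mitraclip": 3.72,
    "hospitalizations_mitraclip": 1.16,
    "lifetime_qaly_mitraclip": 2.32,
    "lifetime_cost_mitraclip": 423817,
    "life_years_omt": 2.9,
    "hospitalizations_omt": 1.51,
    "lifetime_qaly_omt": 1.8,
    "lifetime_cost_omt": 28369
  },
  "free": ["init_mitraclip", "hosp_mitraclip", "init_omt", "hosp_omt"],
  "seed": 20260926,
  "n_starts": 400,
  "objective": 0.000543281237647198,
  "convergence": 0,
  "report": [
    {
      "target": "life_years_mitraclip",
      "goal": 3.72,
      "fitted": 3.75378287947538,
      "rel_error": 0.00908141921381089
    },
    {
      "target": "hospitalizations_mitraclip",
      "goal": 1.16,
      "fitted": 1.15960418504939,
      "rel_error": -0.000341219785007498
    },
    {
      "target": "lifetime_qaly_mitraclip",
      "goal": 2.32,
      "fitted": 2.30000134908797,
      "rel_error": -0.00862010815173583
    },
    {
      "target": "lifetime_cost_mitraclip",
      "goal": 423817,
      "fitted": 423454.728396723,
      "rel_error": -0.000854783086278517
    },
    {
      "target": "life_years_omt",
      "goal": 2.9,
      "fitted": 2.94216753978397,
      "rel_error": 0.0145405309599901
    },
    {
      "target": "hospitalizations_omt",
      "goal": 1.51,
      "fitted": 1.51266284614858,
      "rel_error": 0.00176347427058295
    },
    {
      "target": "lifetime_qaly_omt",
      "goal": 1.8,
      "fitted": 1.77836788655349,
      "rel_error": -0.0120178408036177
    },
    {
      "target": "lifetime_cost_omt",
      "goal": 28369,
      "fitted": 28222.4381201384,
      "rel_error": -0.00516626880967309
    }
  ],
  "fitted_values": {
    "initial_distribution": {
      "mitraclip": [3.48488e-05, 0.961962645, 0.0380022996, 2.066e-07],
      "omt": [0.0002316786, 0.4770451505, 0.5227229168, 2.541e-07]
    },
    "hospitalization_risk": {
      "mitraclip": [0.0028834058, 0.0030154801, 0.0030465714, 0.2370681282],
      "omt": [0.0002489838, 0.0008369658, 0.0858193392, 0.0899882418]
    }
  }
}
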