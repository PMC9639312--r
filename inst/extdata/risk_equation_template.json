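{
  "comment": "Template for a pooled-cohort-equation-style risk model. Fill each stratum with the published coefficients, mean linear predictor and 10-year baseline survival from your source of choice; none are embedded here. Stratum keys are '<sex>_<race_black>' or the single key 'all'. Transforms: identity, log, square; multi-var terms are products (interactions).",
  "strata": {
    "female_0": {
      "terms": [
        {"coef": null, "vars": ["age"], "transform": "log"},
        {"coef": null, "vars": ["total_chol"], "transform": "log"},
        {"coef": null, "vars": ["hdl_chol"], "transform": "log"},
        {"coef": null, "vars": ["sbp"], "transform": "log"},
        {"coef": null, "vars": ["smoking"], "transform": "identity"},
        {"coef": null, "vars": ["diabetes"], "transform": "identity"},
        {"coef": null, "vars": ["age", "smoking"], "transform": "identity"}
      ],
      "mean_lp": null,
      "baseline_survival_10y": null
    }
  }
}
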