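{
  "name": "KSS_ks",
  "description": "Instrumental Knee Society (knee) Score regression model",
  "intercept": 39.680,
  "pain_coefficient": 1.0,
  "pain_item_max": 50,
  "score_bounds": [0, 100],
  "predictors": [
    {"feature": "affected.mc.knee_flexion_extension.nav.stance.median", "coefficient": -0.283, "table_row": 1, "sig": 0.002},
    {"feature": "affected.mc.hip_adduction_abduction.nav.cycle.max", "coefficient": 0.121, "table_row": 2, "sig": 0.007},
    {"feature": "contralateral.mc.foot_progression.angle.stance.median", "coefficient": 0.561, "table_row": 3, "sig": 0.002},
    {"feature": "affected.mc.wrist_dorsi_plantarflexion.nav.stance.max", "coefficient": -0.267, "table_row": 4, "sig": 0.000}
  ],
  "intercept_sig": 0.000
}
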