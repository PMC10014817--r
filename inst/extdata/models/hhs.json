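{
  "name": "HHS",
  "description": "Instrumental Harris Hip Score regression model",
  "intercept": 25.786,
  "pain_coefficient": 1.0,
  "pain_item_max": 44,
  "score_bounds": [0, 100],
  "predictors": [
    {"feature": "affected.mc.hip_flexion_extension.nav.swing.median", "coefficient": 0.076, "table_row": 1, "sig": 0.021},
    {"feature": "contralateral.mc.hip_adduction_abduction.nav.stance.max", "coefficient": 0.075, "table_row": 2, "sig": 0.016},
    {"feature": "contralateral.mc.pelvis_tilt.nav.cycle.median", "coefficient": -0.396, "table_row": 3, "sig": 0.029},
    {"feature": "affected.mc.knee_flexion_extension.nav.cycle.median", "coefficient": 0.232, "table_row": 4, "sig": 0.001},
    {"feature": "affected.mc.knee_flexion_extension.nav.stance.max", "coefficient": 0.043, "table_row": 5, "sig": 0.006},
    {"feature": "contralateral.mc.wrist_deviation.angle.swing.median", "coefficient": -0.235, "table_row": 6, "sig": 0.000}
  ],
  "intercept_sig": 0.000
}
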