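{
  "seq_type": "couplet",
  "feature_names": ["one_minus_cwa", "one_minus_dcwa", "prematurity", "compensatory_ratio", "amp_ratio", "slew_ratio", "width_ratio"],
  "center": [0.99690452497673, 0.569185812214066, 0.696491419654579, 0.966658281796455, 1.11143131169653, 0.773939520081423, 3.33826530612245],
  "scale": [0.807080159432318, 0.466058509529313, 0.0763367210108109, 0.321161499089142, 0.143614003655978, 0.137958777298221, 1.86135188010204],
  "weights": [-1.67201135353332, -0.396388182491379, -4.64234065828034, -2.25222649288559, 0.427951154664045, -2.66224532330151, 0.638723174323115],
  "intercept": 2.9931005122673,
  "threshold": 0.6,
  "seed": 17,
  "data_hash": "0f7e66aa4c47968d1d7dc701f7d2aab9",
  "n_train": 147
}
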