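{
  "seq_type": "single",
  "feature_names": ["one_minus_cwa", "one_minus_dcwa", "prematurity", "compensatory_ratio", "amp_ratio", "slew_ratio", "width_ratio"],
  "center": [1.03941834702191, 0.580916874106865, 0.734920712533026, 1.27098629288618, 1.30182861297438, 0.759859349567285, 3.43824289405685],
  "scale": [0.797262627473639, 0.44912176489147, 0.0387798218624254, 0.0733079802769306, 0.321512352368677, 0.130402662448804, 1.84622548072031],
  "weights": [-3.58210709489603, -1.52456754583704, -2.01664897775244, 0.138803885771739, 2.69726754623882, -3.72695940430681, 0.376263979056905],
  "intercept": 3.16911999372667,
  "threshold": 0.78,
  "seed": 17,
  "data_hash": "a8d067b461d5fc696af77155a3cd47fc",
  "n_train": 580
}
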