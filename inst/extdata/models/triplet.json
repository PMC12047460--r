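{
  "seq_type": "triplet",
  "feature_names": ["one_minus_cwa", "one_minus_dcwa", "prematurity", "compensatory_ratio", "amp_ratio", "slew_ratio", "width_ratio"],
  "center": [0.875727469481799, 0.497902309371271, 0.680342947504054, 0.861029280470198, 1.06037945312374, 0.793022754360717, 3.05031446540881],
  "scale": [0.82338394441563, 0.472854308830511, 0.0775304181071843, 0.306183550423828, 0.126384091592555, 0.133579071570315, 1.86831929527402],
  "weights": [-2.49387795743269, -1.01678904043696, -4.02232844378672, -2.37801727051147, 0.772551161101951, -3.91513443723882, 0.199293892026983],
  "intercept": 3.59131884459309,
  "threshold": 0.44,
  "seed": 17,
  "data_hash": "859d34aa5602690d1e14b8379a28a01f",
  "n_train": 119
}
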