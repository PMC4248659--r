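{
  "Km_LP": 0.00026,
  "Kcat_LP": 129000,
  "Km_GAL": 0.00098,
  "Kcat_GAL": 165000,
  "Km_GLYC": 0.0001,
  "Vmax_GLYC": 143.82,
  "Km_LDH": 0.1,
  "Vmax_LDH": 307.08,
  "K_LS": 564,
  "d_LS": 0.6,
  "K_LZ": 1130,
  "d_LZ": 0.6,
  "K_LR": 564,
  "d_LR": 0.6,
  "d_M": 41.58,
  "d_N": 41.58,
  "GR": 2.5e-09,
  "G": 2.5e-09,
  "n": 1,
  "Kb": 72000,
  "V0": 1,
  "V1": 20,
  "V2": 3.5,
  "T_max": 60000,
  "S": 1000,
  "Ks": 0.00982,
  "K_LA": 0.448,
  "mu_max": 0.8,
  "pH_threshold": 5.5,
  "c0": 6.7,
  "c1": 24,
  "c2": 30,
  "f_conv": 0.8,
  "pyr_per_glc": 2,
  "strict_as_printed": false,
  "repression_form": "printed"
}
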