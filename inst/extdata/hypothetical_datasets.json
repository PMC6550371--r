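{
  "dataset1": {"n_P": 20, "n_A": 20, "xbar_P_mm": -30, "xbar_A_mm": -30, "s2_mm2": 4.6},
  "dataset2": {"n_P": 20, "n_A": 20, "xbar_P_mm": -20, "xbar_A_mm": -30, "s2_mm2": 21.3},
  "dataset3": {"n_P": 20, "n_A": 20, "xbar_P_mm": -20, "xbar_A_mm": -10, "s2_mm2": 4.6}
}
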