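{
  "t1_invivo": {
    "kind": "inversion_recovery",
    "times_s": [0.05, 0.15, 0.35, 0.5, 0.95, 1.995],
    "tr_s": 2.4,
    "inversion_scale": 0.95
  },
  "t2_invivo": {
    "kind": "spin_echo",
    "times_s": [0.037, 0.111, 0.185, 0.259, 0.333, 0.407, 0.48, 0.554, 0.628, 0.702],
    "tr_s": 3,
    "inversion_scale": 0.95
  }
}
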