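{
  "shape": "sharp_square",
  "params": {
    "n_p": 4.7e-7,
    "n_s": 0.001,
    "r_d": 0.025,
    "b_d": 0,
    "alpha_deg": 40,
    "anchoring": "weak"
  },
  "engine": {
    "n_steps": 10000,
    "snapshot_interval": 1000,
    "seed": 1,
    "replicates": 3
  }
}
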