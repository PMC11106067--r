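{
  "seed": 20260101,
  "n_extant": 16,
  "birth": 0.08,
  "death": 0.015,
  "fossil_sampling": 0.05,
  "model": {
    "family": "DEC",
    "d": 0.01,
    "e": 0.002,
    "j": 0
  },
  "root_range": "WNA",
  "boundaries": [30, 5],
  "noise_sd": 0.4,
  "step": 0.4
}
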