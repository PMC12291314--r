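{
  "out": "ojip_out",
  "seed": 1,
  "t0": 20,
  "control": "0h",
  "treatments": ["0h", "4h", "8h", "24h"],
  "variety_pair": ["NH5", "FH18"],
  "alpha": 0.05,
  "correlation_by_variety": false,
  "qa_rc_mode": "quotient",
  "n_reps": 3,
  "noise_cv": 0.02,
  "n_points": 118,
  "plots": false
}
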