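{
  "truth_D": 400,
  "spec": {
    "spot_center": 10,
    "spot_width": 1,
    "n_locations": 9,
    "location_step": 0.6,
    "line_period_ms": 0.7,
    "duration_ms": 35,
    "noise_sd": 0.03,
    "replicates": 7,
    "rng_seed": 42,
    "domain_length": 20
  }
}
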