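# example phptfrax pipeline configuration
"n": 5000
seed: 20260101
horizon: 10
interval_years: 0.5
exclude_antiosteoporosis_med: false
sim:
  censor_rate: 0.235
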