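{
  "kind": "concentration_series",
  "params": {
    "theta_high": 120,
    "theta_low": 60,
    "gamma_high": 0.072,
    "gamma_low": 0.03,
    "logC_mid": -4,
    "slope": 2,
    "concentrations": [1e-05, 3e-05, 0.0001, 0.0003, 0.001, 0.003, 0.01],
    "noise_theta_deg": 1.5,
    "noise_gamma": 0.0008
  },
  "seed": 20,
  "truth": {
    "theta_high": 120,
    "theta_low": 60,
    "logC_mid": -4,
    "slope": 2
  }
}
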