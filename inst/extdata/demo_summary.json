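{
  "seed": 42,
  "n_segments": 8,
  "n_burned_calls": 3,
  "n_unburned_calls": 5,
  "match": {
    "tp": 8,
    "fn": 0,
    "fp": 0,
    "recall": 1,
    "precision": 1
  },
  "classification": {
    "n": 8,
    "unburned_accuracy": 100,
    "burned_accuracy": 75,
    "overall_accuracy": 87.5
  },
  "scorch_regression": {
    "n": 3,
    "slope": 1,
    "r_squared": 1,
    "rmse": 7.32054e-17
  },
  "cvs_agreement": {
    "n": 3,
    "within_10": 1,
    "within_30": 1
  }
}
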