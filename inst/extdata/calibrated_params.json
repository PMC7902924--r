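{
  "low": {
    "EV": {"a": 0.771, "w": 0.079, "c": 0.282},
    "EV-PU": {"alpha": 0.931, "lambda": 1.000, "c": 1.000, "A": 1.0},
    "PVL": {"alpha": 0.557, "lambda": 2.204, "c": 0.311, "A": 0.748},
    "PVL-2": {"alpha": 0.557, "lambda": 2.204, "c": 0.311, "A": 0.748},
    "RANDOM": {}
  },
  "high": {
    "EV": {"a": 0.115, "w": 0.728, "c": 0.819},
    "EV-PU": {"alpha": 0.880, "lambda": 0.129, "c": -0.836, "A": 0.954},
    "PVL": {"alpha": 0.851, "lambda": 4.797, "c": 0.789, "A": 0.099},
    "PVL-2": {"alpha": 0.851, "lambda": 4.797, "c": 0.789, "A": 0.099},
    "RANDOM": {}
  }
}
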