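{
  "threshold": 2,
  "seed": 1,
  "replicates": 100,
  "sim": {
    "n_groups": 4,
    "months": 24,
    "start_size": 5,
    "max_size": 15,
    "join_prob": 0.45,
    "epsilon": 0.1,
    "bouts_per_dyad": 2,
    "generator": "linear",
    "alpha": 10,
    "beta_ordinal": 1,
    "beta_prop": 9,
    "sigma": 1,
    "r1": 0.2,
    "sex": "male",
    "start_period": "2000-01",
    "seed": 1
  }
}
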