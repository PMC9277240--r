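{
  "fixture": "autoreg_negfb",
  "method": "sm",
  "options": {"n_sim": 1500, "K": 2, "mode": "hmm", "restarts": 1},
  "sampler": {"n_iter": 5000, "proposal_frac": 0.02},
  "seed": 1
}
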