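{
  "name": "bd-example",
  "species": [{"name": "P", "kind": "count"}],
  "reactions": [
    {"change": {"P": 1}, "rate": "rho"},
    {"change": {"P": -1}, "orders": {"P": 1}, "rate": "1"}
  ],
  "observed": ["P"],
  "init": [0]
}
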