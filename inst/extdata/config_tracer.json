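{
  "steps": 60,
  "sweeps": 1,
  "neighborhood": "neighbors8",
  "seed": 1
}
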