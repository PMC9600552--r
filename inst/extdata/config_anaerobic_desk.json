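{
  "width": 60,
  "height": 4,
  "horizon": 960,
  "seed": 1,
  "oxygen": {
    "mode": "none"
  }
}
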