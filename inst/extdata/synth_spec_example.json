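{
  "length": 8000,
  "exons": [[927, 1038], [2528, 2858], [4114, 4376], [5465, 5643], [7255, 7604]],
  "background_probs": [0.25, 0.25, 0.25, 0.25],
  "seed": 42
}
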