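{
  "genome": {
    "chrom": ["1", "2", "3", "4"],
    "length": [180000000, 160000000, 140000000, 120000000]
  },
  "regimes": ["WT", "TP53"],
  "n_passages": 24,
  "bottleneck_size": 3000,
  "sampled_passages": {
    "WT": [4, 8, 12, 16, 20, 24],
    "TP53": [8, 16, 24]
  },
  "seed": 5
}
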