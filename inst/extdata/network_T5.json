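{
  "n_genes": 2,
  "w_intra": [-1, -1, 0, 0],
  "w_inter": [1, 0, 1, -1],
  "rule_variant": "threshold_zero",
  "name": "T5"
}
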