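{
  "n_genes": 1,
  "w_intra": 1,
  "w_inter": -1,
  "rule_variant": "threshold_zero",
  "name": "O1"
}
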