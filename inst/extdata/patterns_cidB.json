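{
  "test": "cidB downstream region, BanI + TaqI double digestion of the 1267-1276 bp amplicon",
  "tolerance": 5,
  "patterns": [
    {"name": "1", "fragments": [892, 239, 145]},
    {"name": "2", "fragments": [1028, 239]},
    {"name": "3", "fragments": [861, 239, 167]}
  ]
}
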