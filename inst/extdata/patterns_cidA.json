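{
  "test": "cidA upstream region, ApoI + Hpy188I double digestion of the 778 bp amplicon",
  "tolerance": 5,
  "note": "Small bands (<= 122 bp) co-migrate across variants and are flagged non-discriminating; the beta/gamma class is a single merged RFLP pattern. One source lists 123 instead of 122 bp for the beta/gamma pattern, but only 122 sums to the 778 bp amplicon, so 122 is shipped.",
  "patterns": [
    {"name": "alpha",      "fragments": [471, 122, 57, 53, 51, 24],
     "discriminating": [true, false, false, false, false, false]},
    {"name": "beta/gamma", "fragments": [441, 122, 83, 57, 51, 24],
     "discriminating": [true, false, true, false, false, false]},
    {"name": "delta",      "fragments": [524, 122, 57, 51, 24],
     "discriminating": [true, false, false, false, false]}
  ]
}
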