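{
  "note": "Ordered fragment maps realizing each published RFLP pattern as a constructible amplicon: fragments in left-to-right amplicon order, one enzyme per internal boundary. Fragment order along the amplicon is a package design choice (gels only show the multiset).",
  "maps": [
    {"test": "cidA", "pattern": "alpha",
     "fragments": [471, 53, 122, 57, 51, 24],
     "boundary_enzymes": ["Hpy188I", "ApoI", "Hpy188I", "Hpy188I", "ApoI"]},
    {"test": "cidA", "pattern": "beta/gamma",
     "fragments": [441, 83, 122, 57, 51, 24],
     "boundary_enzymes": ["Hpy188I", "ApoI", "Hpy188I", "Hpy188I", "ApoI"]},
    {"test": "cidA", "pattern": "delta",
     "fragments": [524, 122, 57, 51, 24],
     "boundary_enzymes": ["ApoI", "Hpy188I", "Hpy188I", "ApoI"]},
    {"test": "cidB", "pattern": "1",
     "fragments": [892, 145, 239],
     "boundary_enzymes": ["TaqI", "TaqI"]},
    {"test": "cidB", "pattern": "2",
     "fragments": [1028, 239],
     "boundary_enzymes": ["TaqI"]},
    {"test": "cidB", "pattern": "3",
     "fragments": [861, 167, 239],
     "boundary_enzymes": ["BanI", "TaqI"]}
  ]
}
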