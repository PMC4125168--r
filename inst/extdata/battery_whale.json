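[
  {"name": "A", "classes": null, "fixed": null},
  {"name": "B", "classes": null, "fixed": {"0": 1}},
  {"name": "C", "classes": [[{"type": "clade", "tips": ["killer_whale", "bottlenose_dolphin", "finless_porpoise", "baiji"], "include_stem": true},
                             {"type": "clade", "tips": ["minke_whale", "fin_whale"], "include_stem": true}]], "fixed": null},
  {"name": "D", "classes": [[{"type": "clade", "tips": ["killer_whale", "bottlenose_dolphin", "finless_porpoise", "baiji"], "include_stem": true},
                             {"type": "clade", "tips": ["minke_whale", "fin_whale"], "include_stem": true}]], "fixed": {"1": 1}},
  {"name": "E", "classes": [[{"type": "clade", "tips": ["killer_whale", "bottlenose_dolphin", "finless_porpoise", "baiji", "minke_whale", "fin_whale"], "include_stem": true}]], "fixed": null},
  {"name": "F", "classes": [[{"type": "clade", "tips": ["killer_whale", "bottlenose_dolphin", "finless_porpoise", "baiji", "minke_whale", "fin_whale"], "include_stem": true}]], "fixed": {"1": 1}},
  {"name": "G", "free_ratio": true}
]
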