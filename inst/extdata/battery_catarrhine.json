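[
  {"name": "A", "classes": null, "fixed": null},
  {"name": "B", "classes": null, "fixed": {"0": 1}},
  {"name": "C", "classes": [[{"type": "terminal", "tips": ["human", "orangutan"]}]], "fixed": null},
  {"name": "D", "classes": [[{"type": "terminal", "tips": ["human", "orangutan"]}]], "fixed": {"1": 1}},
  {"name": "E", "classes": [[{"type": "terminal", "tips": ["human", "gorilla", "orangutan"]}]], "fixed": null},
  {"name": "F", "classes": [[{"type": "terminal", "tips": ["human", "gorilla", "orangutan"]}]], "fixed": {"1": 1}},
  {"name": "G", "classes": [[{"type": "clade", "tips": ["human", "chimpanzee", "gorilla", "orangutan"], "include_stem": true}]], "fixed": null},
  {"name": "H", "classes": [[{"type": "clade", "tips": ["human", "chimpanzee", "gorilla", "orangutan"], "include_stem": true}]], "fixed": {"1": 1}},
  {"name": "I", "classes": [[{"type": "terminal", "tips": ["human", "gorilla", "orangutan"]},
                             {"type": "clade", "tips": ["rhesus_macaque", "olive_baboon", "green_monkey"], "include_stem": true}]], "fixed": null},
  {"name": "J", "classes": [[{"type": "terminal", "tips": ["human", "gorilla", "orangutan"]},
                             {"type": "clade", "tips": ["rhesus_macaque", "olive_baboon", "green_monkey"], "include_stem": true}]], "fixed": {"1": 1}},
  {"name": "K", "classes": [[{"type": "terminal", "tips": ["human", "gorilla", "orangutan"]}],
                            [{"type": "clade", "tips": ["rhesus_macaque", "olive_baboon", "green_monkey"], "include_stem": true}]], "fixed": null},
  {"name": "L", "free_ratio": true}
]
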