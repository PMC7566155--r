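[
  {"term": "impossible",         "lower": 0.00, "upper": 0.00},
  {"term": "very improbable",    "lower": 0.00, "upper": 0.10},
  {"term": "improbable",         "lower": 0.05, "upper": 0.35},
  {"term": "as probable as not", "lower": 0.45, "upper": 0.55},
  {"term": "probable",           "lower": 0.65, "upper": 0.95},
  {"term": "very probable",      "lower": 0.80, "upper": 1.00},
  {"term": "certain",            "lower": 1.00, "upper": 1.00}
]
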