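{
  "name": "treatment-communication",
  "description": "Ongoing anticancer treatment delays open end-of-life communication between oncologists, patients and families.",
  "queries": [
    {"label": "open_comm_given_ongoing", "target": "eol_communication=open",
     "evidence": {"cancer_treatment": "ongoing"}},
    {"label": "open_comm_given_discontinued", "target": "eol_communication=open",
     "evidence": {"cancer_treatment": "discontinued"}},
    {"label": "impact_treatment_on_comm", "target": "eol_communication=open",
     "impact": {"variable": "cancer_treatment", "mode": "do"},
     "reported": "40% lower open communication under ongoing treatment"}
  ]
}
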