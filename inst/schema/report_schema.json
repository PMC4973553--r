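{
  "title": "pssScreen run report",
  "required": [
    {"key": "n_candidates", "type": "number"},
    {"key": "n_candidate_svs", "type": "number"},
    {"key": "candidates_per_side", "type": "list"},
    {"key": "cohort_summary", "type": "list"},
    {"key": "terminal_ggg_fraction", "type": "number"},
    {"key": "t_fraction", "type": "number"},
    {"key": "logo", "type": "list"},
    {"key": "stats", "type": "list"},
    {"key": "config", "type": "list"}
  ]
}
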