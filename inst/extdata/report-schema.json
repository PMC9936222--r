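{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "petrad pipeline report",
  "type": "object",
  "required": ["seeds", "config", "cohort", "reduction", "bonferroni",
               "fold_score_means", "rankings", "subgroups"],
  "properties": {
    "seeds": {
      "type": "object",
      "required": ["cohort", "splits", "forest"]
    },
    "config": {
      "type": "object",
      "required": ["mode", "min_voxels", "redundancy_threshold", "n_folds",
                   "k", "occurrence_threshold", "alpha", "discretization"]
    },
    "cohort": {"type": "array"},
    "reduction": {
      "type": "object",
      "required": ["SUV", "TBR"]
    },
    "bonferroni": {
      "type": "object",
      "required": ["threshold", "display", "alpha", "m"]
    },
    "fold_score_means": {"type": "array"},
    "rankings": {"type": "object"},
    "subgroups": {"type": "array"}
  }
}
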