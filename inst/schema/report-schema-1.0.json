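{
  "$id": "glycanShap-report",
  "version": "1.0",
  "description": "Structure of the analysis report written by runPipeline(); enforced by validateReport().",
  "type": "object",
  "required": ["schema_version", "software", "config", "replicates",
               "attribution", "pfi", "dea", "overlaps", "stages"],
  "properties": {
    "schema_version": {"type": "string"},
    "software": {
      "type": "object",
      "required": ["package", "version"]
    },
    "config": {"type": "object"},
    "n_cells": {"type": "integer"},
    "n_genes": {"type": "integer"},
    "n_labeled": {"type": "integer"},
    "replicates": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["split_seed", "best_epoch", "metrics"],
        "properties": {
          "metrics": {
            "type": "object",
            "required": ["train", "validation", "test"],
            "additionalProperties": {
              "type": "object",
              "required": ["accuracyHigh", "accuracyLow", "meanBCE",
                           "rocAUC", "f1Positive"]
            }
          }
        }
      }
    },
    "attribution": {
      "type": "object",
      "required": ["n_explain", "n_background", "base_value",
                   "top_fraction", "n_shap_genes", "shap_genes"]
    },
    "subtype_specific": {"type": ["object", "null"]},
    "pfi": {
      "type": "object",
      "required": ["n_permutations", "top_genes"]
    },
    "dea": {
      "type": "object",
      "required": ["n_significant", "significant_genes"]
    },
    "overlaps": {
      "type": "object",
      "required": ["shap_vs_pfi", "shap_vs_dea"]
    },
    "baselines": {"type": ["object", "null"]},
    "ground_truth_recovery": {"type": ["object", "null"]},
    "stages": {"type": "array"}
  }
}
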