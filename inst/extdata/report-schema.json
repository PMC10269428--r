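{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "fmtomics pipeline report",
  "type": "object",
  "required": ["seed", "filter_reports", "stability", "network", "timing"],
  "properties": {
    "seed": {"type": "integer"},
    "filter_reports": {"type": "object"},
    "stability": {
      "type": "object",
      "required": ["microbiome", "metabolome", "methylome"],
      "properties": {
        "microbiome": {
          "type": "object",
          "required": ["auc", "mean_auc", "sd_auc", "n_features", "top_features"],
          "properties": {
            "auc": {"type": "array"},
            "mean_auc": {"type": "number"},
            "sd_auc": {"type": "number"},
            "n_features": {"type": "integer"},
            "top_features": {"type": "array"}
          }
        },
        "metabolome": {
          "type": "object",
          "required": ["auc", "mean_auc", "sd_auc", "n_features", "top_features"]
        },
        "methylome": {
          "type": "object",
          "required": ["auc", "mean_auc", "sd_auc", "n_features", "top_features"]
        }
      }
    },
    "network": {
      "type": "object",
      "required": ["n_nodes", "n_edges", "rho_cutoff", "edges"],
      "properties": {
        "n_nodes": {"type": "integer"},
        "n_edges": {"type": "integer"},
        "rho_cutoff": {"type": "number"},
        "edges": {"type": "array"}
      }
    },
    "histology_correlations": {"type": "array"},
    "timing": {"type": "object"}
  }
}
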