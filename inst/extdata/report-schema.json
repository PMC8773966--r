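{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "spectsuv analysis report",
  "type": "object",
  "required": ["summaries", "regions", "normality", "mann_whitney", "roc",
               "cutoff", "bins", "overlap", "provenance"],
  "properties": {
    "summaries": {
      "type": "object",
      "required": ["metastatic", "degenerative"],
      "description": "per-category n/min/max/mean/sd of SUVmax, g/mL"
    },
    "regions": {
      "type": "object",
      "description": "lesion counts and percentages per region L/T/P/O"
    },
    "normality": {
      "type": "object",
      "description": "Shapiro-Wilk W and p per category"
    },
    "mann_whitney": {
      "type": "object",
      "required": ["U", "p_value", "method"]
    },
    "roc": {
      "type": "object",
      "required": ["auc", "ci_low", "ci_high", "n_pos", "n_neg", "points"]
    },
    "cutoff": {
      "type": "object",
      "required": ["threshold", "sensitivity", "specificity", "youden_j"]
    },
    "bins": {
      "type": "object",
      "required": ["metastatic", "degenerative"]
    },
    "overlap": {
      "type": "object",
      "required": ["low", "high", "empty", "n_inside", "fraction_inside"]
    },
    "provenance": {
      "type": "object",
      "required": ["package", "version"]
    }
  }
}
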