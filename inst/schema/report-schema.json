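{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "isrsa pipeline report",
  "type": "object",
  "required": ["config", "data", "isrsa", "mds", "indscal"],
  "properties": {
    "config": {
      "type": "object",
      "required": ["models", "n_perm", "seed", "tail", "n_tests", "mds_grid",
                   "indscal_dims", "transform", "focal_roi", "package_version"],
      "properties": {
        "models": {"type": ["array", "string"]},
        "n_perm": {"type": "integer", "minimum": 1},
        "seed": {"type": "integer"},
        "tail": {"enum": ["upper", "two_sided"]},
        "n_tests": {"type": "integer", "minimum": 1},
        "mds_grid": {"type": "integer", "minimum": 10},
        "indscal_dims": {"type": ["array", "integer"]},
        "transform": {"enum": ["ratio", "interval", "ordinal"]},
        "focal_roi": {"type": "string"},
        "package_version": {"type": "string"}
      }
    },
    "data": {
      "type": "object",
      "required": ["study", "n_participants", "n_conditions", "rois"]
    },
    "isrsa": {
      "type": "object",
      "description": "one entry per trait model: per-ROI rho, raw p, Bonferroni-corrected p",
      "additionalProperties": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["roi", "rho", "p", "p_corrected", "n_tests"]
        }
      }
    },
    "mds": {
      "type": "object",
      "required": ["stress1", "converged", "densest_point",
                   "distance_trait_rho", "distance_trait_p"]
    },
    "indscal": {
      "type": "object",
      "required": ["scree", "stress1", "n_dim", "converged",
                   "dimension_interpretation", "weight_trait"]
    }
  }
}
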