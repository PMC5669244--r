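{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "toygold campaign report",
  "type": "object",
  "required": ["facets", "ranking", "provenance"],
  "properties": {
    "facets": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["dG", "err", "estimator", "t_eq", "ess",
                     "conformer_population", "contacts",
                     "mean_simultaneous", "water"],
        "properties": {
          "dG": {"type": "number"},
          "err": {"type": "number", "minimum": 0},
          "estimator": {"enum": ["partition_ratio", "well_depth"]},
          "t_eq": {"type": "number"},
          "ess": {"type": "number", "minimum": 1},
          "conformer_population": {"type": "number"},
          "conformer_se": {"type": "number"},
          "contacts": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["residue", "p", "class"],
              "properties": {
                "residue": {"type": "string"},
                "p": {"type": "number", "minimum": 0, "maximum": 1},
                "class": {"enum": ["none", "moderate", "significant", "strong"]}
              }
            }
          },
          "mean_simultaneous": {"type": "number", "minimum": 0},
          "water": {
            "type": "object",
            "required": ["first_trough_z", "layer1_count", "displaced"],
            "properties": {
              "first_trough_z": {"type": "number"},
              "layer1_count": {"type": "number"},
              "displaced": {"type": "number"},
              "displaced_spread": {"type": "number"}
            }
          }
        }
      }
    },
    "ranking": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["facet", "dG", "err"],
        "properties": {
          "facet": {"type": "string"},
          "dG": {"type": "number"},
          "err": {"type": "number"},
          "significant_vs_next": {"type": ["boolean", "null"]}
        }
      }
    },
    "provenance": {
      "type": "object",
      "required": ["config_hash", "seed", "version"],
      "properties": {
        "config_hash": {"type": "string"},
        "seed": {"type": "integer"},
        "version": {"type": "string"}
      }
    }
  }
}
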