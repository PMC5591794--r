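{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "udise crosswalk rule file",
  "type": "object",
  "required": ["format_version", "systems", "rules"],
  "properties": {
    "format_version": {"type": "string"},
    "description": {"type": "string"},
    "systems": {
      "type": "array",
      "items": {"enum": ["PRINGLE", "VOTE", "NOHL", "PTLTBE"]}
    },
    "rules": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "system", "direction", "source", "target"],
        "properties": {
          "id": {"type": "string"},
          "system": {"enum": ["PRINGLE", "VOTE", "NOHL", "PTLTBE"]},
          "direction": {"enum": ["foreign_to_udise", "udise_to_foreign"]},
          "source": {
            "type": "object",
            "description": "foreign pattern (site/grades/flags/configurations) for foreign_to_udise rules; uDISE pattern (structure/degrees/configurations) for udise_to_foreign rules",
            "properties": {
              "site": {"type": "string"},
              "grades": {"type": "array", "items": {"type": "integer"}},
              "flags": {"type": "array", "items": {"enum": ["N", "P"]}},
              "structure": {"enum": ["N", "V", "Ts", "O", "Tb", "E", "L"]},
              "degrees": {"type": "array",
                          "items": {"type": "integer", "minimum": 0,
                                    "maximum": 2}},
              "configurations": {"type": "array", "items": {"type": "string"}}
            }
          },
          "target": {
            "type": "object",
            "properties": {
              "constraints": {
                "type": "array",
                "items": {
                  "type": "object",
                  "required": ["structure", "degrees"],
                  "properties": {
                    "structure": {"enum": ["N", "V", "Ts", "O", "Tb", "E", "L"]},
                    "degrees": {"type": "array",
                                "items": {"type": "integer", "minimum": 0,
                                          "maximum": 2}},
                    "configurations": {"type": "array",
                                       "items": {"enum": ["AP", "L", "C"]}}
                  }
                }
              },
              "tokens": {
                "type": "array",
                "items": {
                  "type": "object",
                  "properties": {
                    "site": {"type": "string"},
                    "grade": {"type": "integer"},
                    "flag": {"enum": ["N", "P"]},
                    "configuration": {"type": "string"}
                  }
                }
              }
            }
          },
          "lossy": {"type": "boolean"},
          "disjunction": {
            "type": "boolean",
            "description": "constraints are alternatives (finding sits at one of the listed sites), not a conjunction"
          },
          "notation": {"type": "string"},
          "note": {"type": "string"}
        }
      }
    }
  }
}
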