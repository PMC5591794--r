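{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "udise cohort record",
  "type": "object",
  "required": ["patient_id", "system"],
  "properties": {
    "patient_id": {"type": "string", "minLength": 1},
    "system": {"enum": ["UDISE", "PRINGLE", "VOTE", "NOHL", "PTLTBE"]},
    "score": {
      "type": "string",
      "description": "compact score string (uDISE) or space-separated foreign tokens"
    },
    "findings": {
      "type": "array",
      "description": "expanded alternative to 'score'",
      "items": {
        "type": "object",
        "properties": {
          "structure": {"enum": ["N", "V", "Ts", "O", "Tb", "E", "L"]},
          "degree": {"type": "integer", "minimum": 0, "maximum": 2},
          "site": {"type": "string"},
          "grade": {"type": "integer"},
          "flag": {"enum": ["N", "P"]},
          "configuration": {"type": "string"}
        }
      }
    }
  },
  "oneOf": [{"required": ["score"]}, {"required": ["findings"]}]
}
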