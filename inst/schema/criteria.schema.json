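{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Cross-cohort query criteria",
  "type": "object",
  "required": ["datasets"],
  "properties": {
    "datasets": {
      "type": "array",
      "minItems": 1,
      "items": {"type": "string", "minLength": 1}
    },
    "terms": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["concept"],
        "properties": {
          "concept": {"type": "string", "minLength": 1},
          "values": {
            "type": "array",
            "minItems": 1,
            "items": {"type": "string"}
          },
          "min": {"type": "number"},
          "max": {"type": "number"}
        },
        "oneOf": [
          {"required": ["values"]},
          {"required": ["min", "max"]}
        ]
      }
    }
  }
}
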