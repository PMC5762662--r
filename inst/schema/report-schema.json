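{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "traitflux pipeline report",
  "type": "object",
  "required": ["seed", "stages"],
  "properties": {
    "seed": { "type": "integer" },
    "stages": {
      "type": "object",
      "properties": {
        "read":      { "$ref": "#/$defs/stage" },
        "impute":    { "$ref": "#/$defs/stage" },
        "decompose": { "$ref": "#/$defs/stage" },
        "ordinate":  { "$ref": "#/$defs/stage" },
        "rlq":       { "$ref": "#/$defs/stage" },
        "models":    { "$ref": "#/$defs/stage" }
      },
      "additionalProperties": false
    }
  },
  "$defs": {
    "stage": {
      "type": "object",
      "required": ["status"],
      "properties": {
        "status": { "enum": ["ok", "failed", "skipped", "not requested"] },
        "error": { "type": "string" },
        "log": { "type": "object" }
      }
    }
  }
}
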