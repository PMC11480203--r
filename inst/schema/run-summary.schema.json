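{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cooccupy pipeline run summary",
  "type": "object",
  "required": ["package", "seed", "stages"],
  "properties": {
    "package": { "type": "string", "const": "cooccupy" },
    "seed": { "type": "integer" },
    "stages": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["status"],
        "properties": {
          "status": { "enum": ["ok", "failed", "skipped"] },
          "message": { "type": "string" }
        }
      }
    }
  }
}
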