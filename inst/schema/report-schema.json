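{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "mapeval evaluation report",
  "type": "object",
  "required": ["act", "sweep", "provenance"],
  "properties": {
    "act": {
      "type": ["object", "null"],
      "required": ["fC", "fS", "actpm", "tol", "per_electrode"],
      "properties": {
        "fC": {"type": "number", "minimum": 0, "maximum": 1},
        "fS": {"type": "number", "minimum": 0, "maximum": 1},
        "actpm": {"type": "number", "minimum": 0, "maximum": 100},
        "rms": {"type": ["number", "null"]},
        "rms_sd": {"type": ["number", "null"]},
        "tol": {"type": "number", "minimum": 0},
        "per_electrode": {"type": "array"}
      }
    },
    "sweep": {"type": ["array", "null"]},
    "patterns": {
      "type": ["object", "null"],
      "properties": {"per_type": {"type": "array"}}
    },
    "provenance": {
      "type": "object",
      "required": ["entry_id", "master_seed", "tol"]
    }
  }
}
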