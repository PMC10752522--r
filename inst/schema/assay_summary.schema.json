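{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "splenosim assay summary",
  "type": "object",
  "required": ["assay", "config_hash", "seeds", "plateau", "plateau_mean",
               "reached", "criterion"],
  "properties": {
    "assay": {"type": "string"},
    "config_hash": {"type": "string"},
    "seeds": {"type": "array"},
    "plateau": {"type": "array"},
    "plateau_mean": {"type": "number"},
    "plateau_sd": {"type": "number"},
    "reached": {"type": "array"},
    "criterion": {"type": "object"}
  }
}
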