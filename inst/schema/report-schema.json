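{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "agreemix agreement report",
  "type": "object",
  "required": ["indices", "verdicts", "settings", "provenance"],
  "properties": {
    "indices": {
      "type": "object",
      "properties": {
        "ccc": {"type": "number", "minimum": -1, "maximum": 1},
        "msd": {"type": "number", "minimum": 0},
        "cp": {"type": "number", "minimum": 0, "maximum": 1},
        "tdi": {"type": "number", "minimum": 0},
        "cia": {"type": ["number", "null"], "minimum": 0, "maximum": 1},
        "repeatability": {"type": "number", "minimum": 0},
        "loa": {
          "type": "object",
          "required": ["bias", "lower", "upper", "source"],
          "properties": {
            "bias": {"type": "number"},
            "lower": {"type": "number"},
            "upper": {"type": "number"},
            "source": {"enum": ["diff_model", "full_model", "anova", "naive"]}
          }
        }
      }
    },
    "verdicts": {"type": "object"},
    "settings": {
      "type": "object",
      "required": ["cad_delta", "tdi_p", "cp_threshold", "cia_threshold",
                   "loa_multiplier"]
    },
    "provenance": {"type": "object"}
  }
}
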