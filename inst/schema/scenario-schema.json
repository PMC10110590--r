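{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "willisim scenario",
  "description": "Scenario description consumed by read_scenario()/run_scenario(). Version 1.",
  "type": "object",
  "required": ["name", "base", "mode", "regulation"],
  "properties": {
    "format_version": { "const": 1 },
    "name": { "type": "string" },
    "base": {
      "description": "\"reference\" for the bundled network, or a path to a network file",
      "type": "string"
    },
    "edits": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["op", "segment"],
        "properties": {
          "op": { "enum": ["set_diameter", "stenosis", "occlude"] },
          "segment": { "type": "string" },
          "value": { "type": "number", "exclusiveMinimum": 0,
                     "description": "new diameter in mm (set_diameter)" },
          "severity": { "type": "number", "minimum": 0, "maximum": 1,
                        "description": "diameter-change fraction (stenosis)" }
        }
      }
    },
    "sweep": {
      "type": ["object", "null"],
      "required": ["segments", "severities"],
      "properties": {
        "segments": { "type": "array", "items": { "type": "string" } },
        "severities": {
          "type": "array",
          "items": { "type": "number", "minimum": 0, "maximum": 1 },
          "description": "strictly increasing grid"
        },
        "simultaneous": { "type": "boolean", "default": true }
      }
    },
    "mode": { "enum": ["nonlinear", "linear"] },
    "regulation": { "type": "boolean" },
    "params": {
      "description": "autoregulation parameter table, one row per territory",
      "type": "array",
      "items": {
        "type": "object",
        "required": ["territory", "q_target", "r_min", "r_max",
                     "p_lower", "p_upper", "drain"],
        "properties": {
          "territory": { "type": "string" },
          "q_target": { "type": "number", "exclusiveMinimum": 0 },
          "r_min": { "type": "number", "exclusiveMinimum": 0 },
          "r_max": { "type": "number", "exclusiveMinimum": 0 },
          "p_lower": { "type": "number" },
          "p_upper": { "type": "number" },
          "drain": { "type": "number" }
        }
      }
    }
  }
}
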