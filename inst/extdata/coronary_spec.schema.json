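{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "coronary_spec.schema.json",
  "title": "Coronary tree model",
  "description": "Declarative description of a coronary circulation analog: epicardial segments, discrete lesions, myocardial beds, collateral channels, source pressures, probes and named scenarios. Compiled to a DC resistor network (volts = mmHg, amperes = flow units).",
  "type": "object",
  "required": ["segments", "beds"],
  "properties": {
    "name": {"type": "string"},
    "arterial_pressure": {"type": "number", "default": 100, "description": "Arterial source voltage (mmHg equivalent); must exceed venous_pressure."},
    "venous_pressure": {"type": "number", "default": 5, "minimum": 0},
    "inflow_resistance": {"type": "number", "minimum": 1e-9, "description": "Aorta / left-main equivalent series resistance (ohm) between the arterial source and root_node."},
    "root_node": {"type": "string", "default": "ostium"},
    "dominance": {"enum": ["right", "left"], "default": "right"},
    "segments": {
      "type": "array", "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "proximal_node", "distal_node", "resistance"],
        "properties": {
          "id": {"type": "string"},
          "proximal_node": {"type": "string"},
          "distal_node": {"type": "string"},
          "resistance": {"type": "number", "minimum": 1e-9, "description": "Epicardial segment resistance (ohm); values at the 1e-9 minimum compile as ideal wires."}
        }
      }
    },
    "lesions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "segment_id", "resistance"],
        "properties": {
          "id": {"type": "string"},
          "segment_id": {"type": "string", "description": "Must reference an existing segment; the lesion resistor is placed in series within it."},
          "resistance": {"type": "number", "minimum": 1e-9},
          "description": {"type": "string"}
        }
      }
    },
    "beds": {
      "type": "array", "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "feeding_node", "resistance"],
        "properties": {
          "id": {"type": "string"},
          "feeding_node": {"type": "string"},
          "resistance": {"type": "number", "minimum": 1e-9},
          "leaman_weight": {"type": "number", "exclusiveMinimum": 0, "maximum": 100, "description": "Percent of LV mass subtended; used when the resistance is derived by inverse weighting."},
          "drains_to": {"type": "string", "default": "venous", "description": "Venous node; identical for every bed."}
        }
      }
    },
    "collaterals": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "donor_node", "recipient_node", "resistance"],
        "properties": {
          "id": {"type": "string"},
          "donor_node": {"type": "string"},
          "recipient_node": {"type": "string"},
          "resistance": {"type": "number", "minimum": 1e-9}
        }
      }
    },
    "probes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "node"],
        "properties": {"id": {"type": "string"}, "node": {"type": "string"}}
      }
    },
    "scenarios": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "overrides"],
        "properties": {
          "name": {"type": "string"},
          "overrides": {
            "type": "object",
            "additionalProperties": {"type": "number", "minimum": 1e-9},
            "description": "Lesion id -> resistance (ohm) override."
          }
        }
      }
    },
    "metadata": {"type": "object"}
  }
}
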