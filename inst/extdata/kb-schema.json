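{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "tutorplan knowledge base document",
  "description": "Structure of the canonical JSON (and, field-for-field, YAML) knowledge-base files written by save_kb() and read by load_kb(). The package validates documents with its own checker and reports violations with JSON-pointer locations; this file documents the expected shape for external tooling.",
  "type": "object",
  "required": ["format", "version", "concepts", "facts", "profiles", "buks", "patients"],
  "properties": {
    "format": { "const": "tutorplan-kb" },
    "version": { "const": 1 },
    "concepts": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "code", "category"],
        "properties": {
          "id": { "type": "string" },
          "code": {
            "type": "object",
            "required": ["system", "code", "preferred_name"],
            "properties": {
              "system": { "type": "string" },
              "code": { "type": "string" },
              "preferred_name": { "type": "string" }
            }
          },
          "category": { "enum": ["condition", "observation", "treatment_option"] },
          "treatment_subtype": {
            "enum": ["medication", "procedure", "care_plan"],
            "description": "Required when category is treatment_option, forbidden otherwise."
          },
          "parent_id": {
            "type": "string",
            "description": "Id of a more general concept; the parent graph must be acyclic."
          },
          "may_treat": { "type": "array", "items": { "type": "string" } },
          "may_prevent": { "type": "array", "items": { "type": "string" } }
        }
      }
    },
    "facts": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "text", "about_condition"],
        "properties": {
          "id": { "type": "string" },
          "text": { "type": "string" },
          "about_condition": { "type": "string" }
        }
      }
    },
    "profiles": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["condition_id"],
        "properties": {
          "condition_id": { "type": "string" },
          "condition_facts": { "type": "array", "items": { "type": "string" } },
          "findings": { "type": "array", "items": { "type": "string" } },
          "complications": { "type": "array", "items": { "type": "string" } },
          "risk_factors": { "type": "array", "items": { "type": "string" } },
          "treatment_options": { "type": "array", "items": { "type": "string" } },
          "prevention_options": { "type": "array", "items": { "type": "string" } }
        }
      }
    },
    "buks": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "kind", "refers_to", "theme", "bloom", "comprehension", "explanation"],
        "properties": {
          "id": { "type": "string" },
          "kind": { "enum": ["content", "qa"] },
          "refers_to": { "type": "string", "description": "Id of a concept or condition fact." },
          "theme": {
            "enum": ["general", "dosage", "monitoring_tests", "direct_effects",
                     "side_effects", "risky_events", "diet_restrictions"]
          },
          "bloom": { "enum": ["lower", "higher"] },
          "comprehension": { "enum": ["low", "medium", "high"] },
          "explanation": { "$ref": "#/$defs/renderings" },
          "question": {
            "$ref": "#/$defs/renderings",
            "description": "Q&A only; every rendering style must be A or R."
          },
          "choices": {
            "$ref": "#/$defs/renderings",
            "description": "Q&A only; at least two choices."
          },
          "correct_choice": {
            "type": "integer",
            "minimum": 1,
            "description": "1-based index into choices (Q&A only)."
          },
          "sequence_index": {
            "type": "integer",
            "description": "Optional; unique within each (refers_to, theme, bloom) Q&A group."
          }
        }
      }
    },
    "patients": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "comprehension", "preferred_styles", "condition_id", "treatment_request"],
        "properties": {
          "id": { "type": "string" },
          "demographics": { "type": "object" },
          "comprehension": { "enum": ["low", "medium", "high"] },
          "preferred_styles": {
            "type": "array", "minItems": 1, "uniqueItems": true,
            "items": { "enum": ["V", "A", "R", "K"] }
          },
          "condition_id": { "type": "string" },
          "treatment_request": {
            "type": "object",
            "required": ["treatment_option_id"],
            "properties": {
              "treatment_option_id": { "type": "string" },
              "dose": { "type": "string" },
              "rate": { "type": "string" },
              "timing": { "type": "string" }
            }
          },
          "performance_log": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["buk_id", "correct", "tick"],
              "properties": {
                "buk_id": { "type": "string" },
                "correct": { "type": "boolean" },
                "tick": { "type": "integer" }
              }
            }
          }
        }
      }
    }
  },
  "$defs": {
    "renderings": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["style", "text"],
        "properties": {
          "style": { "enum": ["V", "A", "R", "K"] },
          "text": { "type": "string" },
          "asset_ref": { "type": "string" }
        }
      }
    }
  }
}
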