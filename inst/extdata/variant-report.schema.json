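{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "VariantLens variant structural-impact report",
  "type": "object",
  "required": ["variant", "motif_context", "clash_summary", "rotamer_summary",
               "displacement", "interaction_diff", "provenance"],
  "properties": {
    "variant": {
      "type": "object",
      "required": ["chain_id", "residue_number", "from_aa", "to_aa", "label"],
      "properties": {
        "chain_id": { "type": "string" },
        "residue_number": { "type": "integer" },
        "from_aa": { "type": "string", "minLength": 1, "maxLength": 1 },
        "to_aa": { "type": "string", "minLength": 1, "maxLength": 1 },
        "label": { "type": "string" }
      }
    },
    "motif_context": {
      "type": "object",
      "required": ["n_hits", "variant_role"],
      "properties": {
        "n_hits": { "type": "integer" },
        "variant_role": { "type": "string" },
        "hits": { "type": "array" }
      }
    },
    "clash_summary": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["atom_a", "atom_b", "distance", "vdw_sum", "overlap"],
        "properties": {
          "atom_a": { "type": "string" },
          "atom_b": { "type": "string" },
          "distance": { "type": "number", "exclusiveMinimum": 0 },
          "vdw_sum": { "type": "number" },
          "overlap": { "type": "number" }
        }
      }
    },
    "rotamer_summary": {
      "type": "object",
      "properties": {
        "n_rotamers": { "type": "integer" },
        "min_clash_score": { "type": "number", "minimum": 0 },
        "max_clash_score": { "type": "number", "minimum": 0 },
        "best_chi": { "type": "array", "items": { "type": "number" } }
      }
    },
    "displacement": {
      "type": "object",
      "properties": {
        "rmsd_fit": { "type": "number", "minimum": 0 },
        "profile": { "type": "array" },
        "named_atoms": { "type": "array" }
      }
    },
    "interaction_diff": {
      "type": "object",
      "required": ["gained", "lost"],
      "properties": {
        "gained": { "type": "array" },
        "lost": { "type": "array" }
      }
    },
    "protonation": {
      "type": ["object", "null"],
      "properties": {
        "wt": { "type": "array" },
        "mut": { "type": "array" },
        "probabilities": { "type": "array" }
      }
    },
    "provenance": {
      "type": "object",
      "required": ["package_version", "config", "seed"],
      "properties": {
        "package_version": { "type": "string" },
        "config": { "type": "object" },
        "seed": { "type": ["integer", "null"] },
        "stages": { "type": "array" }
      }
    }
  }
}
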