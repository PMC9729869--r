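{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ggppschar characterization report",
  "type": "object",
  "required": ["tool", "version", "inputs", "protein", "motif", "config"],
  "properties": {
    "tool": { "type": "string" },
    "version": { "type": "string" },
    "inputs": {
      "type": "object",
      "required": ["cdna_id", "cdna_length"],
      "properties": {
        "cdna_id": { "type": "string" },
        "cdna_length": { "type": "integer" },
        "genomic_id": { "type": "string" },
        "genomic_length": { "type": "integer" }
      }
    },
    "gene": {
      "type": "object",
      "required": ["exon_count", "intron_count", "all_canonical",
                   "identity", "per_intron"],
      "properties": {
        "exon_count": { "type": "integer" },
        "intron_count": { "type": "integer" },
        "identity": { "type": "number" },
        "score": { "type": "number" },
        "all_canonical": { "type": "boolean" },
        "exons_1based": { "type": "array" },
        "per_intron": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["start_1based", "end_1based", "donor",
                         "acceptor", "canonical"]
          }
        }
      }
    },
    "protein": {
      "type": "object",
      "required": ["length_aa", "mw_kda", "pi", "orf_interval_1based"],
      "properties": {
        "length_aa": { "type": "integer" },
        "mw_kda": { "type": "number" },
        "pi": { "type": "number" },
        "orf_interval_1based": { "type": "array" },
        "orf_length_nt": { "type": "integer" }
      }
    },
    "motif": {
      "type": "object",
      "required": ["type_call", "rule_evidence"],
      "properties": {
        "farm": { "type": "object" },
        "sarm": { "type": "object" },
        "cld": { "type": "string" },
        "upstream5": { "type": "string" },
        "upstream4": { "type": "string" },
        "conserved_domains_I_III_IV": { "type": "string" },
        "type_call": { "enum": ["I", "II", "III", "unclassified"] },
        "rule_evidence": { "type": "string" },
        "nearest_reference": { "type": ["string", "null"] },
        "nearest_identity": { "type": ["number", "null"] }
      }
    },
    "residue_map": {
      "type": "object",
      "required": ["reference_id", "pairs"]
    },
    "config": { "type": "object" },
    "log": { "type": "array" },
    "failed_stage": { "type": "string" },
    "error": { "type": "string" }
  }
}
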