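{
  "schema": "cliviplan-plan-report",
  "version": 1,
  "required_fields": {
    "tool": "object with name and version",
    "provenance": "object (seed, config hash, input checksums)",
    "coefficients": "object mapping tissue class to coefficient",
    "winner": "object with plan_id, approach_label, total_weight",
    "plans": "array of plan entries ordered by rank"
  },
  "required_plan_fields": ["plan_id", "rank", "total_weight", "paths"]
}
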