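{
  "title": "pkaGraph metrics report",
  "type": "object",
  "required": [
    "median_mae",
    "median_rmse",
    "ci90_mae",
    "ci90_rmse",
    "per_repetition",
    "n_repetitions",
    "n_samples"
  ],
  "properties": {
    "median_mae": { "type": "number" },
    "median_rmse": { "type": "number" },
    "ci90_mae": { "type": "array", "items": { "type": "number" } },
    "ci90_rmse": { "type": "array", "items": { "type": "number" } },
    "per_repetition": {
      "type": "object",
      "required": ["mae", "rmse"],
      "properties": {
        "mae": { "type": "array", "items": { "type": "number" } },
        "rmse": { "type": "array", "items": { "type": "number" } }
      }
    },
    "n_repetitions": { "type": "integer" },
    "n_samples": { "type": ["integer", "null"] }
  }
}
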