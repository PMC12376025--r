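{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "autosas candidate-model configuration",
  "type": "object",
  "additionalProperties": false,
  "required": ["models"],
  "properties": {
    "models": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["model_id", "form", "params", "q_min", "q_max"],
        "properties": {
          "model_id": { "type": "string" },
          "form": { "enum": ["guinier", "sphere", "poly_gauss_coil", "mixed"] },
          "q_min": { "type": "number", "exclusiveMinimum": 0 },
          "q_max": { "type": "number", "exclusiveMinimum": 0 },
          "pd_nbins": { "type": "integer", "minimum": 3 },
          "n_restarts": { "type": "integer", "minimum": 0 },
          "params": {
            "type": "object",
            "additionalProperties": {
              "type": "object",
              "additionalProperties": false,
              "required": ["init"],
              "properties": {
                "init": { "type": "number" },
                "lower": { "type": "number" },
                "upper": { "type": "number" },
                "fixed": { "type": "boolean" }
              }
            }
          }
        }
      }
    },
    "fit": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "method": { "enum": ["lm"] },
        "max_iterations": { "type": "integer", "minimum": 1, "default": 2000 },
        "tolerance": { "type": "number", "exclusiveMinimum": 0, "default": 1e-8 },
        "n_restarts": { "type": "integer", "minimum": 0, "default": 0 },
        "seed": { "type": "integer", "default": 1 },
        "chi2_divisor": { "enum": ["n", "n_minus_k"], "default": "n" },
        "smear_nodes": { "type": "integer", "minimum": 5, "default": 21 }
      }
    },
    "selection": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "criterion": { "enum": ["chi2", "occam", "aic", "probability"], "default": "aic" },
        "occam_delta": { "type": "number", "exclusiveMinimum": 0, "default": 1 },
        "gof_threshold": { "type": "number", "exclusiveMinimum": 0, "default": 10 },
        "aic_form": { "enum": ["chi2_plus_2k", "n_log_chi2"], "default": "chi2_plus_2k" },
        "prior_widths": {
          "type": "object",
          "additionalProperties": {
            "type": "object",
            "additionalProperties": { "type": "number", "exclusiveMinimum": 0 }
          }
        }
      }
    }
  }
}
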