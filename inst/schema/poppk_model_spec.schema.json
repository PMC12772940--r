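{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Population PK model specification (retrodict YAML format)",
  "description": "One drug + formulation per file. Units fixed: time h, amount mg, volume L, concentration mg/L. Enforced in R by validate_model_spec(); shipped here as the format's normative description.",
  "type": "object",
  "required": ["drug_name", "formulation", "structure", "typical_params"],
  "properties": {
    "drug_name": { "type": "string" },
    "formulation": {
      "enum": ["IR_tablet", "ER_tablet", "solution", "suspension", "syrup"]
    },
    "structure": {
      "enum": ["one_cpt_oral", "one_cpt_bolus", "two_cpt_oral"]
    },
    "typical_params": {
      "type": "object",
      "description": "Required names depend on structure: one_cpt_oral needs CL_F (L/h), V_F (L), Ka (1/h); one_cpt_bolus needs CL_F, V_F; two_cpt_oral needs CL_F, V_F, Ka, Q_F (L/h), Vp_F (L). Optional: F_rel (fraction in (0,1]), tlag (h, >= 0). All others must be > 0. Ka may not equal CL_F/V_F (flip-flop degeneracy).",
      "properties": {
        "CL_F": { "type": "number", "exclusiveMinimum": 0 },
        "V_F": { "type": "number", "exclusiveMinimum": 0 },
        "Ka": { "type": "number", "exclusiveMinimum": 0 },
        "Q_F": { "type": "number", "exclusiveMinimum": 0 },
        "Vp_F": { "type": "number", "exclusiveMinimum": 0 },
        "F_rel": { "type": "number", "exclusiveMinimum": 0, "maximum": 1 },
        "tlag": { "type": "number", "minimum": 0 }
      },
      "additionalProperties": false
    },
    "covariates": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["target_param", "covariate", "form", "theta"],
        "properties": {
          "target_param": { "type": "string" },
          "covariate": {
            "type": "string",
            "description": "age, weight, height, eGFR, pregnancy_week, a comedication tag, or a formulation tag"
          },
          "form": { "enum": ["power", "proportional", "linear", "exponential"] },
          "theta": { "type": "number" },
          "ref_value": {
            "type": "number",
            "description": "required (> 0) for power; required for linear/exponential; unused for proportional"
          }
        },
        "additionalProperties": false
      }
    },
    "omega": {
      "type": "object",
      "description": "Between-subject lognormal SDs keyed by parameter name; all >= 0.",
      "additionalProperties": { "type": "number", "minimum": 0 }
    },
    "omega_corr": {
      "type": "array",
      "description": "Correlation matrix rows aligned with the omega key order; symmetric, unit diagonal, positive semi-definite.",
      "items": { "type": "array", "items": { "type": "number" } }
    },
    "sigma_add": { "type": "number", "minimum": 0, "description": "additive residual error SD, mg/L" },
    "sigma_prop": { "type": "number", "minimum": 0, "description": "proportional residual error SD, fraction" },
    "ref_covariates": {
      "type": "object",
      "additionalProperties": { "type": "number" }
    }
  },
  "additionalProperties": false
}
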