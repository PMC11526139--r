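{
  "title": "tojpsych stats report",
  "type": "object",
  "required": ["meta", "sample", "shapiro", "anova_jnd", "anova_pse",
               "posthoc_jnd", "pse_model_bf", "clinical_screen",
               "medication_screen", "glm_panss_pos"]
}
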