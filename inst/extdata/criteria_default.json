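[
  {"name": "accuracy", "direction": "maximize", "weight_label": "Very High", "spread": "auto"},
  {"name": "recall", "direction": "maximize", "weight_label": "Very High", "spread": "auto"},
  {"name": "precision", "direction": "maximize", "weight_label": "Very High", "spread": "auto"},
  {"name": "f1_score", "direction": "maximize", "weight_label": "Very High", "spread": "auto"},
  {"name": "roc_auc", "direction": "maximize", "weight_label": "Very High", "spread": "auto"},
  {"name": "log_loss", "direction": "minimize", "weight_label": "Very High", "spread": "auto"},
  {"name": "n_training_samples", "direction": "maximize", "weight_label": "High", "spread": "auto"},
  {"name": "feature_scaling_impact", "direction": "maximize", "weight_label": "High", "spread": "auto"},
  {"name": "hyperparameter_tuning_impact", "direction": "maximize", "weight_label": "High", "spread": "auto"},
  {"name": "irrelevant_attribute_tolerance", "direction": "maximize", "weight_label": "Medium", "spread": "auto"}
]
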