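model,n_training_samples,feature_scaling_impact,hyperparameter_tuning_impact,irrelevant_attribute_tolerance
SVM,0.92,0.92,YES,0.92
Random Forest,0.75,0.08,YES,0.08
Logistic Regression,0.50,0.25,NO,0.50
KNN,0.08,0.92,YES,0.50
Naive Bayes,0.50,0.08,NO,0.75
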