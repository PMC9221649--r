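alternative,accuracy,recall,precision,f1_score,roc_auc,log_loss,n_training_samples,feature_scaling_impact,hyperparameter_tuning_impact,irrelevant_attribute_tolerance
SVM,99.0,99.0,99.5,99.0,99.5,-0.828,0.92,0.92,YES,0.92
Random Forest,97.5,97.0,98.0,97.0,99.0,-0.815,0.75,0.08,YES,0.08
Logistic Regression,97.5,97.0,98.0,97.0,99.0,-0.815,0.50,0.25,NO,0.50
KNN,98.0,98.0,98.5,98.0,99.0,-0.819,0.08,0.92,YES,0.50
Naive Bayes,97.5,97.0,98.0,97.0,99.0,-0.815,0.50,0.08,NO,0.75
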