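{
  "name": "NERVE-ML checklist",
  "schema_version": "1.0",
  "answers": ["Yes", "No", "Unclear", "N/A"],
  "categories": [
    {
      "id": "data",
      "title": "On data and definition of training and testing set",
      "note": "Training and testing data should be statistically independent, such that they are not only different data but also not dependent on each other.",
      "items": [
        {"id": "data-1", "question": "Is there appropriate detail on all data sources (e.g. origin of the data, relevant summary statistics, preprocessing, etc)?"},
        {"id": "data-2", "question": "For data based on epochs/time windows of neural signals (as typical in neural engineering applications), training epochs and testing epochs do not overlap and are not consecutive to each other."},
        {"id": "data-3", "question": "If the data acquisition protocol has a block structure (e.g. same class label for all data points of that block), then the test data comes from different blocks than the training data."}
      ]
    },
    {
      "id": "params",
      "title": "On parameters and hyperparameters selection and optimization",
      "note": "In general, the parameters and settings/hyperparameters should be selected on training/validation data that are completely independent of the testing data.",
      "items": [
        {"id": "params-1", "question": "Are the assumptions of the machine learning approaches or models clearly defined and documented?"},
        {"id": "params-2", "question": "Feature selection was performed using training data only (i.e. not using testing data and not using all data)"},
        {"id": "params-3", "question": "Machine learning settings/hyperparameters are optimized only on training data. This should be the case not only for a classifier, but also for any algorithm whose settings are optimized on data."},
        {"id": "params-4", "question": "Any normalization parameters (e.g. data mean and standard deviation) was estimated on training data only. Testing data should not be included in this estimation (e.g. this estimation should not be made on all available data)"},
        {"id": "params-5", "question": "Hyperparameters (e.g. regularization parameters of SVM or Logistic regression, learning rate, batch size, etc) were selected on training and/or validation data only."},
        {"id": "params-6", "question": "The architecture of a neural network was chosen on training/validation data only."}
      ]
    },
    {
      "id": "metrics",
      "title": "On performance metrics",
      "note": null,
      "items": [
        {"id": "metrics-1", "question": "Are the chosen performance metrics clearly defined and motivated?"},
        {"id": "metrics-2", "question": "For unbalanced test data (e.g. a significantly different amount of testing data per class), was a performance metric that can handle unbalanced data used (e.g. area under the ROC curve or balanced accuracy)?"},
        {"id": "metrics-3", "question": "For a test set with little data, was the chance level performance metric reported (either through analytical calculations or permutation testing) and compared to the actual performance?"},
        {"id": "metrics-4", "question": "Are measures of uncertainty clearly defined and appropriate?"}
      ]
    },
    {
      "id": "conclusions",
      "title": "On scientific conclusions",
      "note": null,
      "items": [
        {"id": "conclusions-1", "question": "Are the key scientific questions clearly related to model results?"},
        {"id": "conclusions-2", "question": "Is it clear how the validation technique relates to the scientific questions?"},
        {"id": "conclusions-3", "question": "Is the practical significance of the performance metrics clearly stated?"},
        {"id": "conclusions-4", "question": "Are statistics run on model results?"},
        {"id": "conclusions-5", "question": "Are statistical assumptions clearly defined?"},
        {"id": "conclusions-6", "question": "Is it clear what level of generalization (e.g. inter-subject, inter-cohort, inter-genotype, etc) is tested?"},
        {"id": "conclusions-7", "question": "Are the limitations of the results clearly stated?"},
        {"id": "conclusions-8", "question": "Are alternative explanations for performance considered?"},
        {"id": "conclusions-9", "question": "Are there concerns about bias or fairness?"},
        {"id": "conclusions-10", "question": "Were specific metrics on bias and fairness identified and evaluated?"}
      ]
    },
    {
      "id": "future",
      "title": "On future use of results and developed technologies",
      "note": null,
      "items": [
        {"id": "future-1", "question": "Will the data be publicly available?"},
        {"id": "future-2", "question": "Will data include necessary metadata for reproducing results?"},
        {"id": "future-3", "question": "Has the data been properly anonymized according to data privacy protection laws and good practices?"},
        {"id": "future-4", "question": "Does anonymization of the data prevent reproduction of the results?"},
        {"id": "future-5", "question": "Is the data stored in a trustworthy repository?"},
        {"id": "future-6", "question": "Is the data license stated?"},
        {"id": "future-7", "question": "Will the code be released in full, including training code, evaluation code, and visualizations?"},
        {"id": "future-8", "question": "Is the code license stated?"},
        {"id": "future-9", "question": "Are dependencies and software versions included?"},
        {"id": "future-10", "question": "Is it stated which results can be fully replicated by the code?"},
        {"id": "future-11", "question": "Is there an appropriately detailed guide on how to use the code?"},
        {"id": "future-12", "question": "Will the trained machine learning model be released?"},
        {"id": "future-13", "question": "Is it clear what resources are necessary to run the code (computational resources, software environment, computational complexity)?"},
        {"id": "future-14", "question": "Is it stated how long any released material will be available?"},
        {"id": "future-15", "question": "It is stated whether permanent record will be created, typically a digital object identifier (DOI)?"}
      ]
    }
  ]
}
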