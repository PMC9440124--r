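.datatable.aware <- TRUE

utils::globalVariables(c(
  "row", "session", "rater_id", "lesion_id", "diagnosis", "confidence",
  "perceived_ai_dx", "perceived_ai_conf", "algorithmic_ai_dx", "histology",
  "expertise", "dx1", "dx2", "conf1", "conf2", "sessions", "n_hist", "n_alg",
  "n_exp", "n"))
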