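Package: aidriver
Title: Active-Inference Driver Agent with Particle Beliefs and
    Expected-Free-Energy Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A particle-based active-inference agent for simulated driving.
    Beliefs over hidden state are a weighted particle ensemble updated by a
    sequential-importance-resampling filter; candidate action sequences are
    scored by expected free energy, the negative sum of a pragmatic value
    (log preference probability of predicted observations) and an epistemic
    value (expected information gain, estimated by a kernel-density entropy
    estimator); actions are selected by cross-entropy-method model predictive
    control over mixed discrete/continuous actions. Ships two closed-loop
    driving scenarios: passing an occluding object that may hide a
    pedestrian, and visual time-sharing between lane keeping and a secondary
    task, together with behavioral metrics (SDLP, steering reversals, glance
    statistics, uncertainty-resolution time) and an experiment registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
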