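Package: adaptrt
Title: Evaluation of Adaptive Radiotherapy Strategies for Prostate SBRT
Version: 0.1.0
Authors@R: person("adaptrt", "maintainers", email = "adaptrt@example.org",
    role = c("aut", "cre"))
Description: Simulation and dosimetric evaluation of daily treatment-plan
    adaptation strategies for ultra-hypofractionated prostate stereotactic
    body radiotherapy (SBRT). Generates reproducible synthetic pelvic
    cohorts with interfractional organ deformation, produces parametric
    dose archetypes for image-guided (IGRT) and adaptive (ART) planning
    strategies, computes dose-volume histograms and PACE-C constraint
    evaluations with a tiered penalty score, and aggregates cohort-level
    statistics including paired t-tests, overlap-volume adaptation triggers
    and penalty-score reduction tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
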