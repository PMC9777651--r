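Package: mptraj
Title: Combined Multimorbidity-Polypharmacy Pattern Trajectories in
    Longitudinal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies combined multimorbidity and polypharmacy patterns in
    longitudinal electronic-health-record panels of older adults and models
    their year-to-year evolution.  Binary chronic-disease and drug-group
    indicators are reduced with principal component analysis for mixed data
    (PCAmix) using the Karlis-Saporta-Spinaki component-retention rule,
    soft-clustered with fuzzy c-means, and modelled with a hidden Markov
    model whose live states correspond to the clusters and which carries
    absorbing death and dropout states; estimation is by multi-restart
    Baum-Welch and decoding by Viterbi.  Patterns are characterised by
    prevalence, observed/expected ratios, exclusivity, transition and
    permanence probabilities and pattern-specific mortality.  A seeded
    synthetic-cohort generator with known ground truth supports testing and
    method evaluation without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
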