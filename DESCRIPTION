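Package: minkedemog
Title: Non-Lethal Demography of Antarctic Minke Whales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Inference chain for estimating the demography of Antarctic
    minke whales (Balaenoptera bonaerensis) from non-lethal field data:
    microsatellite genotype matching with probability-of-identity and
    exact binomial sex-ratio tests; blubber-progesterone pregnancy
    classification by logistic assignment with bootstrap confidence
    envelopes and a probability-sum pregnancy-rate estimator; drone
    (UAS) photogrammetric length estimation with a calibrated
    measurement-error model and highest-posterior-density intervals;
    and maturity-at-length correction of the pregnancy rate via
    MCMC-propagated sex-at-length and maturity-at-length logistic
    curves fitted to commercial catch records. Includes a seeded
    synthetic-cohort generator emulating all five input data streams
    so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
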