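Package: hotspell
Title: Regional Heat-Wave Identification with Imputation of Missing Monitor Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies regional heat waves from a network of weather monitors
    recording daily maximum heat index over the April-September warm season.
    Computes heat index from temperature and relative humidity via the
    Rothfusz regression with the National Weather Service adjustments, imputes
    missing daily maxima by a temporal latent Gaussian model (AR1 plus
    second-order random-walk smooths), per-day ordinary kriging with an
    exponential covariance fitted by restricted maximum likelihood, and a
    spatio-temporal lag model, estimates warm-season percentile thresholds and
    regional benchmark thresholds, applies a two-condition regional heat-wave
    definition, and compares imputation methods by stratified hold-out root
    mean squared prediction error. A synthetic-data generator emulates a
    Florida-like 43-monitor, 40-warm-season record so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    geosphere,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
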