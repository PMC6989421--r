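Package: craniowarp
Title: Landmark-Based RBF Prediction of Facial Distraction Surgery Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates post-operative head and face shape after monobloc or
    facial bipartition distraction in syndromic craniosynostosis. Patient
    datasets (skin and bone surface meshes with named anatomical landmarks)
    are aligned into a standardised skull-base reference frame, normalised
    for shape and size by a radial basis function (RBF) warp of craniometric
    landmarks towards the cohort average, deformed by a cohort-averaged,
    variance-weighted least-squares RBF surgical warp built leave-one-out,
    and de-normalised to yield an individual prediction. Predictions are
    evaluated by signed-distance maps against actual outcomes, with
    per-region summaries and landmark placement reliability reports. A
    synthetic head and cohort generator with a known ground-truth surgical
    field supports end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
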