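Package: harensemble
Title: Homogeneous Neural-Network Ensembles for Smart-Home Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Recognises activities of daily living from binary smart-home
    sensor event streams with a homogeneous ensemble of shallow feed-forward
    networks. Base models are partitioned by time routine (morning, afternoon,
    evening, mixed) and trained with a generated complement class so that each
    model can eliminate itself from decisions outside its routine; outputs are
    fused by support functions with four conflict-resolution rules (highest
    posterior, posterior margin, class-count weighting, and class-count times
    training-accuracy weighting). Includes the event-stream reader/writer,
    30-second windowing and 31-dimensional feature extraction, the dataset
    restructuring pipeline (class merging, under-represented class removal,
    random test split), a synthetic smart-home event simulator with
    controllable inter-class sensor overlap and noise, and an evaluation
    harness that accounts for conflicts and right-but-incorrect cases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
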