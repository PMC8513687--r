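Package: quadcell
Title: Multimodal Cellular Interfacing Array Analysis for Cardiomyocyte Drug
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quad-modality (impedance,
    optical, extracellular potential, stimulation) cellular interfacing array
    experiments on cardiomyocyte and fibroblast cultures. Generates synthetic
    multimodal recordings with known ground truth; extracts per-beat
    opto-mechanical fiducials (contraction slope peak time, contraction peak
    time, relaxation slope peak time, optical cycle duration) and
    extracellular potential features (initiation time, spike amplitude, field
    potential duration); computes stimulation capture rates, the deterministic
    refractory capture model and absolute refractory period estimates;
    reconstructs spatiotemporal contraction-wave movies and activation maps
    from sequentially scanned pixels; assembles time-lapse opacity and
    impedance frames with adhesion and detachment kinetics; and aggregates
    features into dose-response summaries with permutation trend tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rhdf5,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
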