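Package: caudateKD
Title: Reference-Tissue PET Kinetics and Behavioral Analysis for Striatal
    Receptor Knockdown Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for combined PET and behavioral
    studies of striatal dopamine-receptor knockdown in small primates.
    Implements reference-tissue kinetic modeling (simplified reference tissue
    model fitted by basis functions, and Logan graphical analysis with a fixed
    reference efflux constant k2'), parametric BPnd images and region-of-
    interest percent-change summaries, voxelwise general linear models of
    binding against behavioral scores with Gaussian smoothing and cluster
    reporting, a trial-level behavioral battery (errors to criterion,
    change-point segmentation of learning curves into bias, chance and
    improvement stages, win-stay and lose-shift probabilities, side
    stickiness, response-time comparisons, mixed three-way ANOVA), and
    circadian actigraphy summaries (daily weighted center of activity,
    nighttime activity). Includes seeded synthetic-data generators with known
    ground truth so every analysis stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
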