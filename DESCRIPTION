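Package: vrdisparity
Title: Eye-Movement and Binocular-Disparity Statistics for Virtual-Reality Displays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for measuring the statistics of binocular eye movements
    and retinal disparities in head-mounted-display (HMD) environments.
    Reconstructs 3-D scenes from nonlinearly encoded 16-bit depth buffers,
    parses binocular gaze traces into quality-controlled fixations
    (velocity-threshold saccade gating, vergence triangulation), poses the
    two eyes on each fixation with Listing's extended law (L2) torsion, and
    computes Helmholtz retinal disparity fields across the central visual
    field. Includes a fitted horopter surface and Panum's fusional-band
    model for predicting diplopia probability, vergence-accommodation
    conflict profiles with the conflict-minimizing screen distance, and the
    binocular/total field-of-view geometry of per-eye HMD screens under
    horizontal screen shifts and vergence. A synthetic-world module
    generates game-archetype scenes, depth buffers and gaze traces, with an
    exact ray-casting disparity oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
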