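Package: wormkymo
Title: Worm Posture Kymographs, Behavioral State Segmentation, and
    Ratiometric Calcium Trace Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of Caenorhabditis elegans locomotion and neural
    activity from video and fluorescence recordings. Extracts worm midlines
    from image stacks by thinning-based skeletonization, builds spatio-temporal
    body-curvature maps (kymographs), segments behavior into forward, backward
    and omega-turn states, and summarizes inter-omega-turn intervals.
    Quantifies dual-channel (YFP/CFP) cameleon traces as percent ratio change
    from a pre-stimulus baseline with group summaries, and presynaptic puncta
    spacing histograms. Scores plate tracks with radial thermotaxis categories,
    the chemotaxis index, and NaCl approach classifications. Includes a fully
    seeded synthetic generator for labeled worm videos, plate tracks and
    fluorescence traces so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
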