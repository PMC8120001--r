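Package: lesionscope
Title: Quantification of Innate Immune Cell-Lesion Interactions in Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Paco", "Developer", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools for quantifying neutrophil and macrophage behaviour around
    skin lesions (wounds or pre-neoplastic clones) in calibrated multi-channel
    time-lapse movies. Segments neutrophils from cytoplasmic fluorescence by
    thresholding and connected-components labelling, and macrophage nuclei by
    trainable pixel classification; links detections into tracks by optimal
    per-frame assignment with gap closing; rasterises time-keyed manual lesion
    annotations into signed Euclidean distance fields; extracts contact and
    close-proximity interaction events with lineage-specific distance
    thresholds and reports counts, durations, velocities and directionality
    ratios; routes group comparisons through normality testing. Includes a
    seeded synthetic-movie simulator with analytic ground truth so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    clue,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sp,
    digest,
    withr
Config/testthat/edition: 3
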