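Package: flowportrait
Title: FLOW Portraits: Lagrangian Summaries of Widefield Optical Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts widefield optical-imaging movies (for example calcium
    fluorescence reported as relative change, dF/F) into time-varying velocity
    fields with Horn-Schunck optical flow, integrates virtual particles through
    those fields to obtain forward- and backward-time finite-time Lyapunov
    exponent (FTLE) fields, and extracts morphologically processed FTLE ridges
    as concise visual summaries ("FLOW portraits") of where activity initiates,
    terminates and how it spreads. Includes dF/F preprocessing with a
    moving-minimum baseline, variance-based region-of-interest masking,
    pan-cortical wave segmentation, movement and FTLE-intensity traces, a ridge
    count score with a paired t-test comparison, synthetic movie generators
    with ground-truth geometry, and analytic benchmark vector fields (saddle,
    double gyre) with closed-form FTLE for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    igraph,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    optparse
Config/testthat/edition: 3
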