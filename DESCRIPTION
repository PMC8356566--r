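Package: octaslabs
Title: Depth-Resolved OCT Angiography Slab Processing for Infant Retinal Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for handheld optical coherence tomography
    angiography (OCT-A) of the developing perifoveal retinal vasculature.
    Computes flow volumes from repeated B-scans by speckle variance, segments
    the vitreous/ILM, IPL/INL and OPL/ONL retinal boundaries (with import of
    manual corrections), builds anatomically referenced offset slab schemes
    for the superficial, intermediate and deep capillary plexuses (and the
    two-layer SVC/DVC grouping used before the secondary vasculature forms),
    projects en face slabs, sweeps offset combinations into labelled
    collages, applies the display enhancement chain (min-max normalization,
    low-intensity-preserving threshold, row-wise contrast-limited adaptive
    histogram equalization), and composites three-color overlays with
    subtract/lighten blend modes.  Includes a synthetic retinal phantom with
    known layers, plexus labels, flow and pathology so the full pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    rhdf5,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
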