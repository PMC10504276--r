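Package: doctk
Title: Dynamic Optical Coherence Tomography Contrasts and Speckle Phantom Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates time-sequential complex optical coherence tomography (OCT)
    speckle volumes of kidney-like phantoms with known ground-truth dynamics, and
    computes two label-free dynamic-OCT contrasts from repeated B-scan frames: the
    logarithmic intensity variance (LIV), sensitive to second-scale signal
    fluctuations, and a noise-corrected complex-decorrelation contrast (Fast-DOCT),
    sensitive to millisecond-scale dynamics. Includes the two raster scan-timing
    protocols that drive frame acquisition, bulk phase-offset correction, tissue
    surface segmentation, surface-following slab average projections, pseudo-color
    HSV compositing, and metrics (structure diameters, region contrast ratios,
    phenotype reports, correlation-time recovery) for validating the full pipeline
    against phantom ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
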