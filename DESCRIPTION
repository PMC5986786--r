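Package: cardiomorph
Title: Planar Cell Polarity Morphometrics for the Zebrafish Heart Tube
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of epithelial remodelling and planar cell
    polarity in the early zebrafish heart tube. Builds validated
    cell-junction meshes from segmented label rasters or polygon files,
    measures per-cell morphometrics (area, perimeter, circularity,
    orientation axis, elongation), detects transition states (T1 states
    and rosettes, vertices where four or more cells meet) and their
    frequency per 100 cells, fits a landmark-based local anatomical model
    to a traced ventricular outline (Bezier smoothing, centroid, six
    named segments), computes per-cell axial orientation angles against
    the local outline normal with Rayleigh statistics on doubled angles,
    analyses membrane fluorescence line profiles (apical versus basal
    accumulation, co-localisation at transition states, ventricular mean
    intensity), and measures the cardiac looping angle. Includes a
    deterministic synthetic-epithelium generator with a ground-truth
    manifest for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
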