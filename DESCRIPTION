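Package: larvamorph
Title: Outline Morphometrics and Morphospace Disparity of Long-Nosed
    Antlion Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Elliptic Fourier analysis of closed two-dimensional outlines
    (head capsules, stylets and whole bodies of psychopsid lacewing larvae),
    principal-component morphospaces, and convex-hull occupation statistics
    for comparing morphological disparity across geological epochs.  Reads
    outlines from SVG paths, x,y point lists and Freeman chain codes,
    normalizes harmonic coefficients by the first-harmonic ellipse, fits
    covariance-matrix PCA morphospaces with effective-component selection,
    and quantifies per-epoch occupation, hull overlap, subset expansion and
    specimen-accumulation (saturation) curves.  Includes a parametric
    generator of antlion-like larval outlines with labrum morphotypes for
    simulation studies, and a packaged specimen inventory of fossil and
    extant long-nosed antlions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
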