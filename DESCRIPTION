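Package: asternet
Title: Structural Analysis of Self-Assembled Actin Aster Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated structural analysis of star-shaped (aster) actin bundle
    networks in calibrated fluorescence micrographs. Aster centres are detected
    by correlating the image with a bank of thin oriented line kernels, the
    overlaid orientation responses are sharpened by a second, elongated
    correlation pass, and vertices are segmented by blurring, quantile
    thresholding and erosion. Detected centres are connected by a Delaunay
    triangulation from which inter-vertex spacing, neighbour-degree statistics
    and vertex density per square millimetre are derived, the observed density
    is compared with an equilateral-hexagon packing model, and spatial
    homogeneity is assessed by a tile bootstrap with a kernel density estimate.
    A seeded synthetic-image generator produces ground-truthed aster fields
    (jittered triangular lattice, multi-strand bundles, Gaussian point-spread
    function, Poisson and read noise) for validation and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deldir,
    EBImage,
    fftwtools,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
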