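Package: pitscape
Title: Elastic Energy Landscape and AFM Morphometry of Clathrin-Coated Pits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models clathrin-coated pits (CCPs) as spherical caps and computes
    their elastic energy landscape over surface area and radius of curvature:
    membrane bending, membrane tension, clathrin coat bending and clathrin
    polymerization terms, with constrained minimization, tension sweeps and
    constant-area relaxation. Also provides a morphometry chain for high-speed
    atomic-force-microscopy (HS-AFM) topographs of unroofed membranes:
    background leveling, frame registration, spherical-cap fitting restricted
    to the pit apex, clathrin-lattice ridge detection and 3D skeletonization,
    and triskelion inter-arm angle statistics. A synthetic-topograph generator
    with known ground truth (geodesic hexagon/pentagon cap lattices, tip
    dilation, pixel noise) supports end-to-end validation, including simulated
    lattice nanodissection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff,
    MASS,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
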