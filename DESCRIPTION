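Package: vineleaf
Title: Allometric Leaf-Area Models for Vine Leaves from Foliar Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Non-destructive estimation of vine (Vitis vinifera) leaf area
    from ruler-measured foliar descriptors. Implements the allometric model
    MLA = MR * DV * KA with a grid-search calibration of the cultivar-specific
    surface constant KA against scanned reference areas (selection by minimum
    RMSE with a minimum-absolute-mean-error tie-break), per-descriptor
    polynomial leaf-area prediction models with accuracy statistics and
    left-versus-right accuracy comparison, leaf size-class assignment
    (Mesophyll/Macrophyll), and a synthetic five-lobed leaf generator
    (vein-landmark geometry, exact shoelace polygon area, scanline
    rasterization emulating a flatbed scan) so that every stage of the
    pipeline can be exercised and validated without raw leaf scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png
Config/testthat/edition: 3
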