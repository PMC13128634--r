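Package: splatphen
Title: Plant Instance Extraction and Phenotypic Traits from 3D Gaussian
    Splatting Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-reconstruction extraction of individual plant instances
    from multi-plant 3D Gaussian Splatting (3DGS) scenes, and computation of
    phenotypic traits from the extracted instances. Sparse 2D cue masks from
    a handful of seeded views are lifted into per-Gaussian multi-view support
    scores, spatially consolidated by OPTICS density clustering with a
    nearest-neighbour retain step, and chromatically refined with a CIELAB
    Gaussian-mixture filter. Downstream tools group externally supplied
    stem/leaf semantics into organ instances, remap them onto the Gaussian
    primitives, and measure plant height, leaf surface area, leaf area index,
    leaf count, node count and internode lengths. Includes 3DGS PLY input and
    output, video frame-selection policies for reconstruction, a synthetic
    greenhouse scene generator with full ground truth, and evaluation
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    FNN,
    grDevices,
    igraph,
    interp,
    jsonlite,
    mclust,
    png,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
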