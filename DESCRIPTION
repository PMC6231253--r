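Package: leafspace
Title: Quantification of Leaf Intercellular Airspace from X-Ray MicroCT Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the three-dimensional intercellular airspace
    network of plant leaves from laboratory X-ray computed microtomography
    (microCT) image stacks. Provides automatic histogram thresholding (IsoData,
    Li minimum cross-entropy, maximum entropy), automated leaf-disc mask
    creation, mask compositing, small-particle noise removal, per-slice
    connected-component pore analysis with a corner-counting chain-code
    perimeter, leaf porosity, mesophyll surface area exposed to intercellular
    airspace (S_mes), depth-resolved porosity profiles, a Hildebrand-Ruegsegger
    local thickness transform for air-channel diameter mapping, and the
    companion two-dimensional stereological estimator with shape correction
    factor for section images. Includes a deterministic synthetic leaf phantom
    generator with analytic ground truth for validation, and a batch pipeline
    driver with YAML configuration and JSON provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'leafspace-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'io.R'
    'particles.R'
    'metrics3d.R'
    'phantom.R'
    'thickness3d.R'
    'threshold.R'
    'segmentation.R'
    'pipeline.R'
    'stereology2d.R'
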