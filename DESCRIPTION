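Package: mmsla
Title: Multi-Material Stereolithography Print Planning and Fidelity
    Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computational toolkit for multi-material projection
    stereolithography (MMSLA) bioprinting. Represents layered,
    multi-material hydrogel print designs parametrically and rasterizes
    them into grayscale photomask stacks at projector resolution; compiles
    validated machine-event schedules (build-plate motion, sled-driven
    material selection, saline rinse and wick steps) with a
    constant-dose exposure-time model; renders synthetic multi-channel
    fluorescence images of printed feature layers with per-feature ground
    truth; and quantifies print fidelity by blob morphometrics --
    equivalent diameter, circularity (4*pi*area/perimeter^2 with a
    Crofton perimeter estimator), nearest-neighbor centroid distances,
    and post/hole centroid alignment errors judged against the
    projector's pixel-size resolution limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml,
    png,
    tiff,
    pracma,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
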