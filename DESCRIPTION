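Package: odedema
Title: Optic Disk Edema Classification from Fundus Images via Factorized
    Texture-Driven Level Sets
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of color fundus photographs for optic disk
    edema (papilledema) prescreening. Localizes the optic disk from the
    vascular network (parabola-vertex fit for complete networks, straight-line
    convergence for fragmented ones), segments the disk boundary with a
    level-set active contour driven by a factorization of local
    spectral-histogram texture features, extracts 27 texture, vessel, color
    and intensity-profile features, and classifies disks as edematous or
    non-edematous with a linear support vector machine under stratified
    cross-validation. Includes a seeded synthetic fundus phantom generator so
    every stage is testable without clinical image collections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    Matrix,
    e1071,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Classification, Segmentation, Visualization
RoxygenNote: 7.3.3
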