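Package: MagSnake
Title: Gradient Vector Flow Active Contours with Magnetostatic Concavity Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric active contours (snakes) driven by a semi-dynamic
    gradient vector flow (GVF) external force field. A tangent-versus-force
    angle detector locates "false" (stalled) contour segments on a stopped
    snake, and a magnetostatic corrective force computed from hypothetical
    electric currents along the object boundary (a Biot-Savart style sum)
    is added to the field near the false segments, letting the contour
    converge into deep, narrow boundary concavities that defeat plain GVF.
    Includes a synthetic shape generator with ground-truth boundaries,
    boundary-distance metrics, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, grDevices, utils, png, tiff, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'imaging.R'
    'gvf.R'
    'snake.R'
    'falseDetect.R'
    'magnet.R'
    'fixtures.R'
    'metrics.R'
    'driver.R'
    'cli.R'
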