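Package: dirqa
Title: Quality Assurance of Deformable Image Registration via Vortex Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the curl (vorticity) of 3-D displacement vector fields
    produced by deformable image registration and derives a scalar vortex map
    whose hotspots flag implausible, non-anatomical warping. Provides
    thresholded hotspot detection with connectivity-based labeling,
    plausibility classification against configurable curl bands,
    structure-proximity reporting, color-coded slice overlays, and a JSON QA
    report. Ships a synthetic module (constant-HU phantom with cylinder and
    cube inserts, analytic and random smooth deformations with closed-form
    curl, streak and HU-offset artifact injectors, image warping, and a
    minimal demons registration fixture) so the whole QA loop runs without
    external data. Reads and writes MetaImage, NRRD, and NIfTI volumes with
    full physical metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
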