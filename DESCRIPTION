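Package: atlasanchor
Title: Anchoring Serial Brain Section Images to 3D Reference Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless registration of serial 2D microscopic brain-section
    images to arbitrary oblique planes of a 3D reference atlas (Allen Mouse
    CCFv3, Waxholm Space rat). Sections are placed by anchoring vectors
    (o, u, v) expressed in atlas voxels; the package converts between image
    pixels, atlas voxels and physical stereotaxic coordinates, resamples
    template and segmentation volumes along anchoring planes to produce
    matching atlas plates, propagates anchorings across a section series,
    and reads and writes the QuickNII interchange formats (XML/JSON series
    descriptors, PNG plates, big-endian .flat label rasters, palette JSON).
    Includes a synthetic-atlas generator for fully self-contained testing
    and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    rlang,
    xml2,
    jsonlite,
    RNifti,
    png
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
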