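Package: slicereg
Type: Package
Title: Multimodal Registration of 2D Cross-Sections into 3D Image Volumes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Registers a 2D image (for example a PET scan or a histological
    cut) into a 3D grayscale volume (for example an NMR dataset) by exhaustive
    per-slice rigid alignment scored with normalized mutual information. The
    2D/3D problem is decomposed into independent 2D/2D alignments, one per
    volume slice, distributed over a worker pool through a dynamic job queue.
    Includes a seeded multimodal phantom generator for ground-truth
    validation, NIfTI and PNG/TIFF input, and JSON result serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, jsonlite, parallel, png, RNifti, stats, tiff, tools, utils, withr,
    yaml
LinkingTo: Rcpp
Suggests: optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
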