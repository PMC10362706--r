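Package: facevol
Title: Projection-Method Facial Soft-Tissue Volumetry and CBCT Voxel Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Measures buccal facial soft-tissue volume (STV) and its change
    (STVC) from serial 3D facial surface scans by the projection method:
    scans are rigidly registered on the upper third of the face, a
    mid-sagittal reference frame is constructed from orthogonal laser
    traces, the buccal region is delimited by landmark-connecting surface
    paths, transferred between time points through a +/-10 mm extruded ring
    model, and integrated as the volume projected onto the mid-sagittal
    plane. Companion tools compute hard-tissue volume change (HTVC) from
    serial CBCT volumes by threshold segmentation, ROI Boolean subtraction
    and box-gated voxel counting, per-vertex signed deviation summaries
    (mean, SD, RMS), ICC(2,1) reliability statistics, and synthetic phantom
    generators with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
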