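Package: anthromesh
Title: Non-Contact Anthropometry from 3D Body Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Derives body measurements from 3D body meshes without contact
    equipment: reads and writes STL/OBJ geometry, reduces vertex counts with
    an information-loss guard, renders perspective depth maps and multi-view
    snapshot sets, detects eleven body seed points on frontal silhouettes,
    segments the body into parts, and measures lengths, circumferences and
    volumes of major body parts from planar mesh cross-sections. Includes a
    parametric A-pose humanoid generator with analytic ground truth for every
    stage, camera-placement selection from ratio-error grids, and per-part
    error and accuracy aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
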