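Package: sraguide
Title: Patient-Specific Guide-Wire Planning and Drill-Guide Design for Hip
    Resurfacing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational pipeline for patient-specific guide-wire
    positioning in hip surface replacement arthroplasty. Fits the femoral head
    sphere and the anatomical femoral neck axis on triangle surface meshes of
    the proximal femur, turns them into a drill plan with cortex-clearance
    checks, parametrically generates the custom snap-fit drill-guide jig
    (hemispherical-plus cage, anterior neck support, four cutting knives,
    drill-guide cylinder) as a watertight mesh with STL export, and evaluates
    achieved drill accuracy from simulated post-operative scans by trimmed
    iterative-closest-point registration, drill-channel cylinder fitting and
    angular-deviation decomposition into frontal, axial and sagittal
    components. Includes a seeded synthetic proximal-femur generator with
    exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
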