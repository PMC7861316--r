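Package: rtplanscore
Title: Plan Scoring, Achievable-DVH Prediction and Beam Selection for
    Lung IMRT Planning Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computational back-end for a knowledge-model tutoring system
    for lung/mediastinum intensity modulated radiation therapy (IMRT)
    planning.  Provides geometry-aware containers for 3D dose grids and
    structure masks with DICOM-RT (RTDOSE, RTSTRUCT) adapters and a native
    fixture format; a dose-volume histogram (DVH) engine with the standard
    plan-quality metrics (Dx%, VxGy, mean/max/min dose, Paddick
    conformation number, conformity index, max-dose location); a 164-point
    plan scoring rubric with raw and percentage scores, plan comparison
    and cohort aggregation; a knowledge-based achievable-DVH prediction
    model for organs at risk built on distance-to-target histogram (DTH)
    principal components; a beam-efficiency-index selector for separated
    coplanar beam bouquets; and a parametric synthetic thorax phantom and
    plan-dose synthesizer so the whole system is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
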