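Package: kneemark
Title: Automated Anatomical Landmarking and Morphometry of Knee Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated anatomical landmark annotation and morphometric
    measurement for triangular surface meshes of the distal femur and proximal
    tibia. A template mesh is rigidly aligned and then elastically deformed onto
    each subject's bone+cartilage surface, imposing the template topology and
    thereby dense anatomical correspondences. Expert landmark annotations are
    propagated through these correspondences onto a cohort mean shape,
    averaged with equal observer weighting, propagated back to each subject,
    and refined at locally extreme positions (most anterior/posterior,
    medial/lateral, proximal/distal vertex). Linear measurements of the
    tibiofemoral joint are computed by axis projection in a reference frame
    anchored on the femoral posterior condylar line. The package also ships
    the full intra-/inter-observer and inter-method agreement toolbox
    (quartile/IQR outlier flagging, two-way ANOVA intraclass correlation,
    Bland-Altman limits of agreement, success-rate-at-tolerance curves) and a
    synthetic condyle-phantom generator with analytic ground truth so the
    whole pipeline can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
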