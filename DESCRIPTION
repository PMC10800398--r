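Package: lumbosim
Title: Trephine Osteotomy Geometry and Finite-Element Biomechanics on
    Parametric Lumbar Spine Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates targeted-puncture trephine osteotomy at the L4/5
    interspace and the biomechanical consequences of the resection.  A seeded
    parametric L3-L5 phantom (vertebral bodies with cortical shell, posterior
    elements, discs with offset nucleus, endplates, facet joints and seven
    ligament groups) stands in for patient CT reconstructions.  Trephine
    trajectories are planned on the intervertebral reference plane at entry
    angles of 20-70 degrees with 7/8/9 mm tools and a 5 degree second-attempt
    offset; resected bone volume is computed by constructive-solid-geometry
    Boolean intersection with a Monte Carlo oracle; and a linear tetrahedral
    finite-element model with truss ligaments evaluates range of motion and
    maximum von Mises stress of the intact and resected motion segment under
    a 400 N follower load plus 10 Nm pure moments in six directions.  Cohort
    summaries with paired t-tests and one-way ANOVA reproduce the reporting
    conventions of the underlying study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
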