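Package: spinemorph
Title: Quantitative Morphometry of the Developing Spine and Rib Cage
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Landmark-based morphometry for embryonic spine and rib
    phenotyping. Fits cubic splines through vertebral-body centres and
    quantifies sagittal geometric curvature (reciprocal of the osculating
    circle radius) per vertebra, measures spine height and endplate wedge
    angles, classifies wedged and fused vertebrae, and scores rib
    centerlines for curved length and inflection-count tortuosity.
    Includes fused-joint proportion summaries from histology joint tables,
    the group-comparison statistics used in skeletal developmental studies
    (one-way ANOVA with Tukey post-hoc tests and unpaired t-tests per
    vertebral location), and a seeded generator of synthetic chick-like
    specimens for control and immobilised groups across embryonic days
    E5-E9, calibrated to published cohort statistics, for validating the
    full measurement pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'spline.R'
    'spine-curvature.R'
    'wedging.R'
    'ribs.R'
    'histology.R'
    'group-stats.R'
    'generator.R'
    'io.R'
    'pipeline.R'
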