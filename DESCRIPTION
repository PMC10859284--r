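Package: morphnet
Title: Single-Subject Gray-Matter Morphological Similarity Networks
Version: 0.1.0
Authors@R:
    person("Morphnet", "Developers", email = "morphnet@example.org",
           role = c("aut", "cre"))
Description: Builds single-subject structural brain networks from gray-matter
    density volumes by correlating 3x3x3-voxel cube textures (maximized over the
    24 proper cube rotations), resizes the cube-pair similarities onto a labeled
    parcellation atlas, applies Fisher r-to-z and proportional sparsity
    thresholding, and computes global and nodal graph-theory measures (degree,
    clustering, betweenness, characteristic path length, global efficiency,
    small-worldness with degree-preserving null models). Includes life-event
    questionnaire scoring with stress-group cut-offs, hub detection,
    covariate-adjusted group comparison with Benjamini-Hochberg FDR, partial
    correlation with stress level, permutation-based network statistics on edge
    connectivity strength, a synthetic-data generator for end-to-end testing,
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    digest,
    optparse
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
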