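Package: cfrwplan
Title: Collision-Free Reachable Workspace Planning for Multi-Needle
    Thermal Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic multiple-needle insertion-trajectory planning for
    robot-assisted thermal ablation of large liver tumors. Obstacles
    (vessels, ribs, previously inserted needles) are modelled as posed
    super-quadric implicit surfaces; for each needle the boundary of its
    collision-free reachable workspace around every obstacle is traced as
    a one-dimensional curve per horizontal layer by pseudo-arclength
    continuation of a Jacobian-singularity criterion built on an
    interior-point (barrier) closest-pair system.  The optimal entry
    point on a parametric skin surface is then selected by a
    four-quadrant grid-refinement search, needles are planned
    sequentially, and each inserted needle becomes an obstacle for its
    successors.  Includes deterministic synthetic scene generators, JSON
    scene/plan serialization, boundary export and layer plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
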