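Package: cliviplan
Title: Risk-Weighted Corridor Planning for Approaches to the Inferior Clivus
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated surgical decision-making for the inferior clivus.
    Represents the retro-condylar skull base as a voxel label map, spans it
    with a corridor graph of tetrahedral paths anchored on named landmarks,
    scores every path by injury risk (tissue volume times risk coefficient)
    minus surgical freedom (free operative space volume), and selects the
    minimum-total-weight plan by shortest-path search on the corridor DAG.
    Includes a parametric synthetic skull-base phantom generator, a cohort
    simulator for anatomical variation, exact Fisher 2x2 and Spearman
    rank-correlation statistics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
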