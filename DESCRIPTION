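Package: equivs
Title: Conformer-Ensemble Bioactivity Prediction with Equivariant Graph
    Networks and Attention-Based Multiple Instance Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Ligand-based virtual screening from ensembles of 3D molecular
    conformers. Molecules are standardized, embedded into multiple ETKDG
    conformers, MMFF94-optimized, aligned and hydrogen-stripped, then encoded
    as molecular graphs with 74-dimensional atom features, 12-dimensional
    bond features and concatenated per-conformer coordinates. A graph
    convolutional topological encoder and stacked E(3)-equivariant
    message-passing layers learn per-conformer representations that are
    aggregated by attention-based deep multiple instance learning into a
    molecule-level bioactivity prediction (in -logM units), with
    conformer-level predictions and attention coefficients available for
    optimal-conformer interpretation. Includes bioactivity-table curation
    (activity-type filtering, bucketed value integration, target-scale
    filtering), dataset splitting, training with a combined bag/instance
    loss, evaluation metrics, and synthetic task generators for end-to-end
    testing. Chemistry perception (standardization, conformer embedding,
    force-field optimization, SDF input/output) is delegated to RDKit through
    a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
SystemRequirements: Python (>= 3.8) with the RDKit package available on the
    interpreter found on PATH (or pointed to by option 'equivs.python' /
    environment variable EQUIVS_PYTHON).
Config/testthat/edition: 3
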