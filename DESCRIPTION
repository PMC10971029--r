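Package: varidyn
Title: Variant Effects on Protein Complex Dynamics from Trajectory Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores how protein variants alter the collective dynamics and
    inter-subunit interactions of a two-chain complex from multi-frame
    coordinate ensembles. Implements least-squares (Kabsch) superposition,
    Cartesian principal component analysis of C-alpha coordinates with a
    one-sigma median-shift classifier, residue-pair distance monitors,
    free-energy landscapes over principal-component score pairs,
    switched-cutoff nonbonded interaction energies decomposed by domain
    pair, and a down-sampled resampling t-test for significance calls.
    Ships a synthetic-ensemble generator with planted collective modes and
    interface-charge perturbations so the whole pipeline is testable
    without molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
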