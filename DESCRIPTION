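Package: confscape
Title: Quantifying Conformational Heterogeneity in Tetrameric Receptor Ensembles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify conformational heterogeneity in ensembles of
    fitted atomic models of tetrameric ligand-gated ion channels (AMPA-type
    glutamate receptors and their auxiliary-subunit complexes). Measures
    N-terminal-domain dimer tilt/splay angles against a reference receptor,
    performs principal component analysis of C-alpha coordinate ensembles
    without superposition and writes RMSD-scaled morph trajectories, measures
    ligand-binding-domain rotation angles about vertical anchor axes,
    quantifies category proportions (e.g. domain-swapped versus non-swapped
    particles) across repeated classifications with consensus statistics, and
    fits receptor desensitization and recovery kinetics from current traces.
    Includes a deterministic synthetic-data generator with planted ground
    truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
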