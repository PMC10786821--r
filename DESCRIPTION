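Package: molwgan
Title: Scaffold-Constrained Molecular Graph Generation with a Wasserstein GAN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: De novo design of quinoline-scaffold molecules with a Wasserstein
    generative adversarial network whose generator and discriminator operate on
    relational molecular graphs (one-hot adjacency and node-feature tensors).
    Provides the full desk-scale pipeline: SMILES-to-tensor featurization with
    explicit hydrogens, formal charges and tetrahedral chirality; deterministic
    synthetic quinoline libraries for offline testing; dataset filtering and
    serialization; relational graph convolutional generator and critic trained
    with the Wasserstein objective and gradient penalty; validity, connected
    validity, scaffold-retention, novelty and uniqueness metrics with an
    exhaustive-generation stopping rule; chemical-space embedding via circular
    fingerprints and t-SNE; and a drug-likeness screen (Lipinski Rule of 5,
    Ertl synthetic-accessibility score, pluggable Tox21-style toxicity
    predictor interface).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
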