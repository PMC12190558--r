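Package: gluegen
Title: Ligase-Conditioned Junction-Tree Variational Autoencoder for Molecular Glue Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generative modeling of E3-ligase-specific small molecules
    ("molecular glues") with a junction-tree variational autoencoder that is
    conditioned on the binding-site residue sequence of an E3 ubiquitin ligase
    (CRBN, VHL, MDM2). Provides torsion-aware molecular graph featurization,
    junction-tree (clique) decomposition and reassembly, protein-sequence
    encoders with two latent-fusion strategies, beta-annealed training with
    teacher-forced reconstruction metrics, conditional decoding, and screening
    analytics: ADMET-style threshold filtering, docking-score affinity
    stratification, Murcko-scaffold frequency analysis, generative-set metrics
    (validity, uniqueness, novelty, QED, Lipinski adherence), and 2D
    chemical-space projection. A deterministic synthetic fixture generator
    makes the whole pipeline runnable at desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    ChemmineR,
    ChemmineOB,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
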