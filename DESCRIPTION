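Package: SubInhib
Title: Substrate-Inhibition-Aware Enzyme Variant Design and Pathway Flux
    Modelling
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for engineering metabolic pathways limited by enzyme
    substrate inhibition, built around the lycopene cyclase bottleneck of
    carotenoid biosynthesis. Provides position-specific scoring matrix
    (PSSM) construction from protein multiple sequence alignments and a
    reader for the psiblast ASCII PSSM dialect; a mutant-library design
    pipeline that ranks substitutions toward more conserved residues,
    pools top-ranked substitutions into doubles, and down-selects them by
    PAM30 distance clustering; Haldane substrate-inhibition kinetics
    (evaluation, nonlinear least-squares fitting, and AICc-based model
    selection against Michaelis-Menten); a flow-restrictor ODE model of
    the GGPP to lycopene to beta-carotene pathway segment with its
    analytic runaway threshold; fermentation arithmetic (media molar C/N
    ratio, OD600 to dry-cell-weight conversion, carotenoid selectivity,
    volumetric productivity, fold improvement); and seeded generators for
    synthetic alignments and assay curves.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, Proteomics, SystemsBiology
RoxygenNote: 7.3.3
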