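Package: SEFtools
Title: Shannon Entropy Framework Descriptors for QSAR Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes Shannon entropy framework (SEF) molecular descriptors
    from string representations of molecules: token-frequency Shannon
    entropies of SMILES, SMARTS and InChIKey strings, per-atom fractional
    Shannon entropies with zero padding to a common width, and bond-type
    frequency profiles with their bond entropy. Assembles configurable
    descriptor matrices (optionally with molecular weight and folded
    ECFP4/Morgan fingerprint bits), exports per-atom node feature tables
    for graph models, and provides the reference baseline models used to
    benchmark such descriptors: a Tanimoto-similarity k-nearest-neighbour
    predictor over ECFP4 fingerprints and a grid-searched random forest,
    together with the standard QSAR evaluation metrics. A deterministic
    synthetic molecule generator with known token, atom and bond
    compositions supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    ranger,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SEFtools-package.R'
    'tokenize.R'
    'parse.R'
    'entropy.R'
    'featurize.R'
    'baselines.R'
    'synth.R'
    'cli.R'
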