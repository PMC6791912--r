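Package: chloroMS
Title: Classification of Organochlorine EI-MS Spectra from Fast
    Topological Molecular Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for binary classification of electron-ionization mass
    spectra of organochlorine compounds from 1D/2D molecular descriptors.
    Parses SMILES into hydrogen-suppressed molecular graphs, computes
    Kier-Hall electrotopological state (E-state) indices and atom-type
    aggregates, carbon-type counts, bond-order-weighted path counts,
    Barysz-matrix eigenvector descriptors, extended topochemical atom and
    Galvez charge indices; labels spectra by molecular-ion ([M]) and
    dechlorination ([M-35]) peak intensity criteria; selects descriptors by
    sensitivity analysis of a preliminary neural-network ensemble; trains
    one-hidden-layer perceptron ensembles with BFGS; and evaluates models
    with accuracy, ROC/AUC, cumulative gain and class-separation
    statistics. Includes a seeded generator of valence-valid synthetic
    organochlorine datasets with a planted structure-class relationship.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
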