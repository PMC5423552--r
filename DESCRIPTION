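Package: nanospectra
Title: Single-Molecule Protein Identification from Sub-Nanopore Current Blockades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying single protein molecules from the ionic
    current blockade signals ("nanospectra") they produce while translocating
    through a sub-nanometre pore. Implements event detection and fractional
    blockade conversion for raw current traces, three models that predict a
    theoretical nanospectrum from an amino-acid sequence (mean quadromer
    volume, support vector regression on volume-group compositions, and
    random forest regression on per-position volume/hydrophilicity pairs),
    database search scored by the coefficient of determination with
    decoy-calibrated p-values, consensus averaging of repeated translocations,
    fluctuation-frequency protein length estimation via Gaussian mixtures,
    and a trace simulator that provides ground truth for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    mclust,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
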