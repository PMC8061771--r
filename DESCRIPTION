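Package: AdductIMS
Title: Adduct-Resolved Analysis of MALDI Imaging Mass Spectrometry Lipid Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying cation adducts (H+, Na+, K+) of membrane
    lipids in MALDI imaging mass spectrometry of colon mucosa. Provides an
    exact-mass registry for phosphatidylcholine and sphingomyelin species, a
    ground-truthed synthetic tissue-raster simulator, spectrum preprocessing
    (TIC normalization, peak alignment, relative-intensity filtering),
    per-spectrum class-wise adduct-ratio estimation with deconvolution of
    isobaric channel overlaps, and spatial statistics of the sodium/potassium
    adduct pair ratio along crypt paths and across tissue compartments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AdductIMS-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'preprocess.R'
    'deconvolve.R'
    'io.R'
    'layout.R'
    'lipid-registry.R'
    'simulate.R'
    'spatial.R'
    'pipeline.R'
    'plots.R'
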