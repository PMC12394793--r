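Package: AcylMS
Title: Direct Detection of Long-Chain S-Acylated and Prenylated Peptides by
    Tandem Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying and quantifying lipidated peptides in
    bottom-up proteomics without acyl-biotin exchange. Implements a
    fragmentation model for long-chain S-acylated (thioester) and prenylated
    (thioether) peptides with activation-specific neutral-loss channels and
    diagnostic ions, spectrum annotation with backbone ion coverage and
    modification-site localization, in-silico tryptic digestion with
    variable-modification peptidoform enumeration, a miniature target-decoy
    database search with q-value estimation, and an MS1 extracted-ion
    chromatogram stability-quantification assay with normalization and
    significance testing. A synthetic-spectrum simulator provides
    ground-truth fixtures for every component.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    xml2,
    mzR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'chem-core.R'
    'peptidoform.R'
    'digestion.R'
    'fragmentation.R'
    'spectra-io.R'
    'mzml.R'
    'annotation.R'
    'localization.R'
    'search.R'
    'stability.R'
    'simulate.R'
    'zzz.R'
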