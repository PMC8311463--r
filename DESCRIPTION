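Package: cyclopep
Title: Discovery and Characterization of Cyclotides from Peptidomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A desk pipeline for the mass-spectrometric discovery and
    characterization of cyclotides, the head-to-tail cyclic cystine-knot
    peptides of Violaceae and related plant families.  Implements
    monoisotopic mass arithmetic for cyclic and linear peptides across
    cysteine derivatization states, screening of MALDI peak lists for the
    reduction / carbamidomethylation / ring-opening mass-shift series that
    identifies six-cysteine cyclic peptides, in-silico site-specific
    proteolysis of cyclic backbones (GluC, trypsin, chymotrypsin) with
    missed cleavages, b/y fragment-ion annotation of MS/MS spectra with
    Ile/Leu resolution from chymotryptic evidence, four-parameter logistic
    IC50 and Michaelis-Menten curve fitting for protease-inhibition assays,
    and identity-scored homology ranking with cystine-loop decomposition
    and Moebius/bracelet subtype classification.  Seeded generators emulate
    every input format so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
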