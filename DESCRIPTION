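Package: edtaqc
Title: EDTA-Aware Quality Control and Blood Ionome Quantification from 1D 1H NMR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated processing of serum/plasma 1H NMR spectra collected in
    the presence of the anticoagulant EDTA. Chains linear chemical-shift
    prediction models anchored on the glucose anomeric doublet to assign free
    EDTA and Ca/Mg/Zn-EDTA multiplets, deconvolutes them with
    template-constrained Voigt lineshapes (including asparagine subtraction
    for the Zn-EDTA singlet), converts integrals into absolute ion
    concentrations through a sensitivity-normalized universal calibration that
    harmonizes spectrometers at different fields, and removes EDTA-related
    signals with baseline reconstruction for metabolomics-ready spectra.
    Ships a synthetic serum-EDTA spectrum generator with full ground truth so
    every stage is testable without real cohorts. Reads Bruker processed-data
    directories, JCAMP-DX and two-column text spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
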