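Package: acinet
Title: Seizure Dynamics of the Anterior Cingulate-Insula Network from SEEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of directed functional coupling and cortical excitability
    between the anterior cingulate and anterior insular cortices across seizure
    periods in stereo-EEG. Implements frequency-specific nonlinear correlation
    (h2) with lag scanning and a direction index, spectral parameterization of
    power spectra into aperiodic (1/f) and Gaussian oscillatory components, an
    excitation-inhibition proxy from the aperiodic exponent, period
    segmentation around seizure onset, paired statistics with
    Benjamini-Hochberg correction, and a seeded synthetic SEEG generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
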