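Package: larvasense
Title: Biohybrid Larval Motion Sensing: Electrostatic Generation Model and
    Spectral Activity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward model and analysis chain for a biohybrid "living sensor"
    that reads out the vitality of anhydrobiotic chironomid larvae from the
    voltage they induce on interdigital comb electrodes. Provides a synthetic
    generator of larval, machine-driven and control recordings and of rendered
    larva videos; a quasi-static finite-difference electrostatic model of
    induced-charge power generation by a charged moving body over a comb
    electrode array; the spectral measurement pipeline (segmentation, moving
    average, Hamming-window FFT amplitude spectra, band-limited activity
    index, dominant-peak detection); condition-level statistics with Student's
    t-tests; and video motion tracking by binarization and boundary tracing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    EBImage,
    jsonlite,
    Matrix,
    png,
    pracma,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
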