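Package: frcc
Title: Fractional Mel Cepstral Coefficients for Two-Class Speaker-State Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of fractional Mel cepstral coefficients (FrCC) from
    short-time speech frames via a unitary discrete fractional Fourier
    transform, together with two classification back-ends for two-class
    speaker-state (normal versus deceptive) detection: a from-scratch Fisher
    linear discriminant with threshold decision, and discrete-observation
    hidden Markov models trained by Baum-Welch over a vector-quantized
    feature stream. Includes an optimal-order angle sweep over the fractional
    order, evaluation statistics (accuracy, sensitivity/specificity, vector
    variance ratios), a seeded generator of labeled two-class chirp corpora
    emulating an 8 kHz / 16-bit recording protocol, and plain WAV/text
    input-output with a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
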