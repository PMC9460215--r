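Package: bowelwarn
Title: Defecation Pre-Warning from Bowel Sounds with a Semi-Supervised GAN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies short bowel-sound segments as carrying or not carrying a
    defecation tendency using a semi-supervised generative adversarial network
    (SSGAN) whose discriminator is a (K+1)-class one-dimensional convolutional
    classifier, the extra class flagging generator output. Provides a
    parameterized synthetic bowel-sound simulator (Poisson bursts of damped
    sinusoids in the 100-500 Hz band over a Gaussian noise floor), WAV input and
    output, FFT-based preprocessing into fixed-length spectral frames,
    declarative architecture specifications with shape-trace validation, the
    combined supervised/unsupervised adversarial training loop, a plain CNN
    baseline, confusion-matrix diagnostics (accuracy, specificity, sensitivity)
    with multi-task macro averaging, and a recording-level warning rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
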