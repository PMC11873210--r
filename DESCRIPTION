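Package: soundloc
Title: Bayesian Ideal-Observer Modelling of Human Sound Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a Bayesian ideal-observer model of human sound
    localization for sources whose spectrum is unknown to the listener.
    Directions are decoded by maximum a posteriori matching of interaural
    time difference and spectral features (log-magnitude, interaural
    spectral difference, binaural/ipsilateral/positive spectral gradients)
    against head-related transfer function (HRTF) templates under a
    multivariate Gaussian likelihood. The covariance combines
    psychoacoustic measurement noise with an ecologically valid
    source-spectrum prior estimated from audio corpora. Includes an ERB
    auditory filterbank, SOFA HRTF input, synthetic HRTF and corpus
    generators, spherical-harmonics HRTF resampling, rippled-spectrum
    stimulus generation, and a Monte-Carlo experiment engine computing
    polar error rates, great-circle error maps and response-attractor
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
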