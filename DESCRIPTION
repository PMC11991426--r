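Package: spikevein
Title: Unsupervised Spiking Convolutional Networks with Adaptive Firing
    Threshold for Vein-Pattern Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an unsupervised two-layer spiking convolutional
    network for finger-vein biometric recognition. Grayscale region-of-interest
    images are filtered with Gabor and difference-of-Gaussians kernels,
    converted to cumulative spike-wave tensors by intensity-to-latency
    rank-order coding, and processed by non-leaky integrate-and-fire
    convolutional layers whose firing threshold adapts to the mean membrane
    potential of each sample. Features are learned with a stabilized
    spike-timing-dependent plasticity rule under winner-take-all competition
    and lateral inhibition, and classified with one-vs-rest linear support
    vector machines. Includes a synthetic vein-image generator, chi-square
    percentile feature selection, and biometric evaluation (accuracy, FAR,
    FRR, EER) with broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    e1071,
    png,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
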