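Package: snnxattr
Title: Gradient-Based Feature Attribution for Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spike-level (3D) and pixel-level (2D) feature-attribution maps
    for spiking neural networks trained with surrogate-gradient
    backpropagation. Implements a minimal leaky integrate-and-fire network
    with differentiable surrogate spike functions, forward simulation and
    backpropagation through time; neural encoders for grayscale images
    (time-to-first-spike, Poisson rate, phase, burst coding); gradient and
    integrated-gradients attribution (SNN-Grad3D/2D, SNN-IG2D/3D) plus
    spike-activation-map baselines (SAM, inverted SAM); and a quantitative
    evaluation harness with deletion/insertion perturbation curves against a
    random control and jitter/deletion noise-robustness sweeps at the input
    and network level. Ships synthetic class-separable image and event-stream
    generators so the full pipeline runs without external data, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
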