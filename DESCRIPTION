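Package: clockwave
Title: Spatial Waves of Circadian Clock Gene Expression in Seedlings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and image-analysis toolkit for spatial waves of
    circadian clock gene expression in Arabidopsis seedlings. Implements a
    growing-template Kuramoto phase-oscillator model with organ-specific
    intrinsic periods, local nearest-neighbour coupling and 24-h light
    forcing; a synthetic luminescence time-lapse renderer; kymograph
    extraction from luminescence stacks via grey-level-weighted centroids,
    seventh-degree centerline fits and Bresenham-rasterized normal sections;
    single-scale Morlet continuous-wavelet phase mapping; organ-level rhythm
    analysis (FFT-seeded damped-cosine period estimation, Butterworth peak
    detection) and Kuramoto order-parameter synchrony quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    signal,
    pracma,
    minpack.lm,
    igraph,
    tiff,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
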