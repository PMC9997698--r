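Package: alphasync
Title: Long-Range Alpha-Band Phase Synchronization Analysis for Covert
    Visuospatial Attention EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse long-range alpha-band phase
    synchronization in covert visuospatial attention EEG experiments. Provides
    a synthetic multichannel EEG generator with controllable frontoparietal
    von Mises phase coupling and parieto-occipital power lateralization, a
    deterministic preprocessing chain (zero-phase Butterworth filtering, EOG
    trial rejection, channel repair, mirror padding, Hjorth Laplacian), Morlet
    wavelet time-frequency decomposition, phase-locking value (PLV),
    inter-site phase clustering (ISPC) and phase linearity measurement (PLM)
    connectivity, individual-alpha-frequency estimation and interhemispheric
    power lateralization indices, Monte-Carlo and cluster-based permutation
    statistics, and single-trial attended-side decoding with RBF support
    vector machines plus shrinkage-LDA and Riemannian minimum-distance-to-mean
    baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
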