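Package: dirflow
Title: Directed Connectivity Analysis for Oscillatory Multichannel Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of directed (effective) connectivity in
    epoched multichannel oscillatory recordings such as resting-state EEG or
    MEG. Provides epoch-level spectral preprocessing with individualized
    frequency bands, frequency-domain beamformer source reconstruction (DICS),
    multivariate autoregressive modelling with information-criterion order
    selection, partial directed coherence (PDC) and its renormalized variant
    (RPDC), time-resolved PDC via dual extended Kalman filtering, surrogate
    and time-reversal significance testing of directed edges, group
    statistics, and support-vector-machine classification of band-resolved
    connectivity features. Includes a synthetic-cohort generator with
    ground-truth directed networks for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
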