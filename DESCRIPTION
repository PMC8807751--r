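Package: eegstgcn
Title: Spatial-Temporal Graph Convolutional Networks with Dynamic
    Connectivity for Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classification of four-class motor-imagery
    electroencephalography (EEG) with a spectral graph convolutional
    network whose channel graph is initialised from pairwise mutual
    information and updated during training from cosine similarities of
    learned node embeddings.  Provides EEG input/output (EDF and a
    plain-text matrix container), zero-phase band-pass filtering,
    cue-locked epoching, differential-entropy and band-power feature
    extraction with hemispheric and caudal asymmetry variants, a toolbox
    of adjacency-matrix constructions (geometric, cosine, Jaccard,
    mutual-information, k-nearest-neighbour, distance-threshold, random
    and hybrid schemes), spatial and temporal attention, Chebyshev
    polynomial graph convolution, flooding-regularised training with
    stratified cross-validation, and a synthetic EEG generator with
    planted block connectivity for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
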