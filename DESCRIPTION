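Package: adstgnn
Title: Adaptive Spatial-Temporal Graph Networks for EEG Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements an adaptive spatial-temporal graph neural network for
    emotion recognition from differential-entropy (DE) EEG features. The model
    combines temporal and spatial attention over per-second feature windows,
    an input-dependent learnable channel adjacency with graph-smoothness
    regularization, attention-modulated Chebyshev spectral graph convolution,
    temporal convolution, and domain-adversarial subject alignment via a
    gradient reversal layer. Includes within-subject and leave-one-subject-out
    cross-validation protocols, ablation switches, a synthetic multi-subject
    DE-feature generator with controllable class structure, graph structure
    and subject shift, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
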