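Package: surgtcn
Title: Multi-Task Multi-Stage Temporal Convolutional Networks for
    Hierarchical Surgical Workflow Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint online recognition of coarse surgical phases and
    fine-grained steps in procedure videos with a multi-task multi-stage
    causal temporal convolutional network (MTMS-TCN). Provides the
    two-level phase/step ontology with validation and file I/O, a
    semi-Markov synthetic workflow generator with class-conditional
    Gaussian feature emission, a multi-task frame-level backbone contract
    with median-frequency class balancing, causal dilated residual
    temporal stages with per-stage phase and step heads and streaming
    (online) inference, frame-wise evaluation metrics with video-level
    cross-validation, and ribbon-plot visualization of label timelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
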