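Package: ctelcan
Title: Cross-Modal Transformer with Adversarial Alignment for Cross-Subject
    Physiological Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training and evaluation toolkit for cross-subject emotion
    recognition from multimodal physiological signals (EEG, EOG, EMG, GSR).
    Implements a cross-modal Transformer feature extractor (per-modality
    pointwise projection, sinusoidal positional encoding, scaled dot-product
    attention of each modality against the concatenated multimodal context,
    and a stack of pre-norm encoder layers), a conditional self-attention GAN
    that synthesizes label-consistent feature-space samples for augmentation,
    and a learning-classifying adversarial network in which modality and
    subject classifiers are attached to the feature learner through a
    gradient reversal layer so that fused representations become modality-
    and subject-invariant while remaining emotion-discriminative. Includes a
    seeded synthetic multimodal data generator, leave-one-subject-out
    cross-validation, ablation and robustness harnesses, and a command-line
    interface. All forward and backward passes are implemented natively
    (RcppArmadillo), with no external deep-learning runtime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
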