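Package: gesturekit
Title: Personalized Surface-EMG Gesture Recognition and Haptic Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale toolkit for personalized surface electromyography
    (sEMG) gesture classification and vibrotactile message encoding. Provides
    a parameterized synthetic generator of multi-channel sEMG envelope
    recordings with controllable inter-user variability, sliding-window
    segmentation and z-score standardization with persisted scaler parameters,
    a lightweight one-dimensional convolutional network classifier trained
    with Adam and early stopping, a versioned file-backed per-user model
    registry, streaming inference with batch-equivalence guarantees,
    personalized-versus-cross-user evaluation experiments, and an encoder that
    maps gestures or text onto spatiotemporal vibration patterns for a
    ten-motor arm sleeve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
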