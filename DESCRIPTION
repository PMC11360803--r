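Package: shodnn
Title: Sea Horse Optimization Training of Small Neural Networks for
    Wearable-Sensor Gesture Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements the Sea Horse Optimization (SHO) swarm
    metaheuristic and uses it to train the weights and biases of a small
    fully connected neural network that classifies medication-intake hand
    gestures from wrist-worn inertial-sensor features. Includes readers
    and writers for per-sensor CSV streams, sliding-window segmentation
    and feature extraction, z-score normalization, a synthetic gesture
    generator for the five-step pill-taking vocabulary, stratified
    ten-fold cross-validated evaluation with accuracy, sensitivity,
    precision and F1, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
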