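Package: behavbench
Title: Synthetic Long-Term Behavior Simulation and Change-Detection Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates year-long synthetic records of daily living for a single
    monitored resident -- coded (activity, home location, heart-rate level)
    triples on a 5-minute grid -- from a hierarchical hidden Markov model with
    Gaussian start-time and duration distributions. Injects six types of gradual
    behavioral change (starting time, duration, disappearance, swap, location,
    heart rate) and their pairs, slices datasets into overlapping multi-day
    window features, and benchmarks supervised, semi-supervised and
    unsupervised anomaly detectors (RBF-kernel SVM, small convolutional
    network, one-class SVM, stacked auto-encoder, weighted K-means, deep
    clustering with a convolutional auto-encoder) by confusion-matrix metrics
    and lead-time of prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    e1071,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
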