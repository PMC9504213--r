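Package: protostream
Title: Task-Free Continual Learning for Sensor-Based Activity Recognition
    with Prototypical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a task-free, data-incremental continual-learning
    framework for wearable-sensor human activity recognition. A
    convolutional-recurrent encoder maps fixed-length multichannel windows to
    an embedding space in which each activity class is represented by a
    prototype (its mean embedding). Prototypes evolve online with streaming
    batches via running averages, are stabilised against obsolescence by
    replay-based adaptation with a refresh ratio, and catastrophic forgetting
    is mitigated by experience replay from a small per-class exemplar buffer
    together with a margin-based contrastive loss. Includes the streaming
    experiment protocol (base/new class split, non-i.i.d. batch scheduler,
    sliding-window segmentation), online-finetuning and offline-supervised
    baselines, forgetting and intransigence evaluation measures, time-series
    augmentations, and a synthetic multichannel stream generator for
    self-contained experimentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
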