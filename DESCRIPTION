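Package: ratecap
Title: Channel Capacity of Repeated Category Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Information-theoretic analysis of repeated category ratings,
    treating a human rater as a noisy communication channel. Builds
    input/output pairs from repeated ratings of the same stimuli (the input
    being each stimulus's rounded mean rating, optionally in a leave-one-out
    variant), estimates mutual information in bits from contingency tables
    with an optional Miller-Madow small-sample correction, sweeps source
    entropy across block sizes to trace the information-transmission curve,
    and fits a saturating-exponential asymptote to estimate channel
    capacity. Includes a synthetic rater-channel generator (Gaussian noise
    discretized onto a bounded Likert scale) so the whole pipeline can be
    exercised and validated without behavioral data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
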