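Package: codewindow
Title: Sliding-Window Deductive Coding of Interview Transcripts with
    Few-Shot Text Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automating deductive qualitative coding of long
    interview transcripts with a binary few-shot text classifier. Builds
    the few-shot chat prompt for each code in a codebook, scans transcripts
    with an overlapping sliding window of sentences, detects coded segments
    by peak detection over per-sentence positive-window counts (moving-average
    smoothing, adaptive threshold escalation under a segment word cap), pools
    and batches detected segments for per-code summarization, and assembles a
    case-by-code summary matrix for constant-comparative analysis. Ships the
    complete three-level evaluation protocol (confusion metrics and Cohen's
    kappa with Landis-Koch interpretation, relative code-frequency factors,
    binary occurrence accuracy, summary-rating tallies), a deterministic
    keyword mock classifier with controllable false-positive and
    false-negative rates, and a seeded synthetic corpus generator with
    planted coded fragments so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
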