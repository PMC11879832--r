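test_that("uniform 50-word sentences give the textbook window layout", {
  corpus <- uniform_corpus(12, 50)
  cfg <- pipeline_config()
  w <- make_windows(corpus, cfg)
  expect_equal(w$first_sentence, c(0L, 2L, 4L, 6L, 8L, 10L))
  expect_equal(w$start_offset, c(0L, 100L, 200L, 300L, 400L, 500L))
  expect_equal(w$last_sentence[1], 5L)  # six 50-word sentences = 300 words
  # every sentence covered; interior sentences in at most the design overlap
  cover <- table(unlist(purrr::map2(w$first_sentence, w$last_sentence, seq)))
  expect_equal(sort(unique(as.integer(names(cover)))), 0:11)
  expect_lte(max(cover), max_window_overlap(cfg))
})

test_that("a single over-cap sentence becomes its own window", {
  corpus <- counted_corpus(400)
  expect_warning(w <- make_windows(corpus, pipeline_config()),
                 class = "codewindow_overcap_window")
  expect_equal(nrow(w), 1)
  expect_equal(w$first_sentence, 0L)
  expect_equal(w$word_count, 400L)
})

test_that("windows on random transcripts match the brute-force oracle", {
  cfg <- pipeline_config()
  for (seed in 1:5) {
    set.seed(seed)
    wc <- sample(5:60, 200, replace = TRUE)
    corpus <- counted_corpus(wc)
    w <- make_windows(corpus, cfg)
    o <- oracle_windows(wc, cfg$window_max_words, cfg$min_stride_words)
    expect_equal(w$first_sentence, unname(o[, "first"]))
    expect_equal(w$last_sentence, unname(o[, "last"]))
    expect_equal(w$word_count, as.integer(unname(o[, "words"])))
    # invariants: full coverage, strictly increasing starts with proper gaps
    covered <- unique(unlist(purrr::map2(w$first_sentence, w$last_sentence, seq)))
    expect_setequal(covered, 0:199)
    expect_true(all(diff(w$start_offset) >= cfg$min_stride_words))
  }
})

test_that("design overlap and initial threshold reproduce the worked parameters", {
  expect_equal(max_window_overlap(pipeline_config(300, 75)), 4L)
  expect_equal(max_window_overlap(pipeline_config(300, 300)), 1L)
  expect_equal(max_window_overlap(pipeline_config(300, 80)), 4L)
  # empirical check of the 300/80 case on a uniform transcript
  corpus <- uniform_corpus(100, 10)
  w <- make_windows(corpus, pipeline_config(300, 80))
  cover <- table(unlist(purrr::map2(w$first_sentence, w$last_sentence, seq)))
  expect_equal(max(cover), 4)

  expect_equal(initial_threshold(pipeline_config(300, 75, 0.51)), 3L)
  expect_equal(initial_threshold(pipeline_config(300, 300, 0.51)), 1L)
  expect_equal(initial_threshold(pipeline_config(800, 100, 0.51)), 5L)  # ceil(4.08)
})

test_that("positive coverage counts match the double-loop oracle", {
  corpus <- uniform_corpus(12, 50)
  w <- make_windows(corpus, pipeline_config())

  v0 <- verdicts_from(w, rep(FALSE, nrow(w)))
  expect_equal(count_positive_coverage(w, v0, "code_01", 12), rep(0L, 12))

  one <- tibble::tibble(case_id = "c1", window_id = 1L, code_id = "z",
                        positive = TRUE)
  w1 <- tibble::tibble(case_id = "c1", window_id = 1L, first_sentence = 3L,
                       last_sentence = 8L, word_count = 300L, start_offset = 150L)
  expect_equal(count_positive_coverage(w1, one, "z", 12),
               c(0L, 0L, 0L, rep(1L, 6), 0L, 0L, 0L))

  set.seed(99)
  for (i in 1:5) {
    pos <- sample(c(TRUE, FALSE), nrow(w), replace = TRUE)
    v <- verdicts_from(w, pos)
    expect_equal(count_positive_coverage(w, v, "code_01", 12),
                 oracle_coverage(w$first_sentence, w$last_sentence, pos, 12))
  }
  expect_error(count_positive_coverage(w, v0[-1, ], "code_01", 12),
               class = "codewindow_missing_verdict")
})

test_that("moving-average smoothing shrinks at edges and preserves constants", {
  expect_equal(smooth_counts(c(0, 0, 4, 0, 0), 1), c(0, 4/3, 4/3, 4/3, 0))
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(smooth_counts(x, 0), x)
  expect_equal(smooth_counts(rep(2.5, 10), 3), rep(2.5, 10))
  for (r in 0:4) expect_equal(smooth_counts(x, r), oracle_smooth(x, r))
})

test_that("segment grouping equals the run-finding oracle", {
  wc <- rep(10L, 4)
  seg <- group_segments(c(3, 3, 0, 3), 3, wc)
  expect_equal(seg$first_sentence, c(0L, 3L))
  expect_equal(seg$last_sentence, c(1L, 3L))
  expect_equal(seg$word_count, c(20L, 10L))

  expect_equal(nrow(group_segments(c(1, 2, 1), 3, rep(5L, 3))), 0)

  set.seed(7)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    smoothed <- round(runif(n, 0, 4), 2)
    wcs <- sample(3:30, n, replace = TRUE)
    thr <- runif(1, 0.5, 3.5)
    seg <- group_segments(smoothed, thr, wcs)
    runs <- oracle_runs(smoothed >= thr)
    expect_equal(nrow(seg), length(runs))
    for (j in seq_along(runs)) {
      expect_equal(c(seg$first_sentence[j], seg$last_sentence[j]), runs[[j]])
      expect_equal(seg$word_count[j], sum(wcs[(runs[[j]][1] + 1):(runs[[j]][2] + 1)]))
    }
  }
})

test_that("threshold escalation caps segment size and drops to empty when needed", {
  # a 3,500-word run at level >= 3 containing a 2,000-word level-4
  # sub-plateau: threshold must escalate from 3 to 4, keeping only the
  # sub-plateau, which fits the cap
  wc <- rep(100L, 60)
  smoothed <- c(rep(3, 15), rep(4, 20), rep(0, 25))
  cap <- 3000L

  # oracle: re-run grouping at each threshold until the cap is met
  thr <- 3
  repeat {
    seg <- group_segments(smoothed, thr, wc)
    if (nrow(seg) == 0 || max(seg$word_count) <= cap) break
    thr <- thr + 1
  }
  expect_equal(thr, 4)
  expect_gt(max(group_segments(smoothed, 3, wc)$word_count), cap)
  seg4 <- group_segments(smoothed, 4, wc)
  expect_lte(max(seg4$word_count), cap)
  expect_equal(seg4$first_sentence, 15L)
  expect_equal(seg4$last_sentence, 34L)
  # the escalation core agrees with the per-threshold oracle
  esc <- codewindow:::escalate_one(smoothed, wc, 3L, cap)
  expect_equal(esc$threshold_used, 4L)
  expect_equal(esc$segments, seg4)

  # degenerate all-positive transcript escalates to emptiness and warns
  corpus2 <- uniform_corpus(50, 100)          # 5,000 words
  w2 <- make_windows(corpus2, pipeline_config())
  v2 <- verdicts_from(w2, rep(TRUE, nrow(w2)))
  expect_warning(
    out <- detect_with_escalation(corpus2, v2, "code_01",
                                  pipeline_config(smoothing_radius = 0)),
    class = "codewindow_dropped_code"
  )
  expect_equal(nrow(out$segments), 0)
  max_count <- max(out$scores$raw_count)
  expect_equal(out$threshold_used, max_count + 1L)
})

test_that("segments below the cap pass through at the initial threshold", {
  corpus <- uniform_corpus(30, 50)
  w <- make_windows(corpus, pipeline_config())
  # one positive window -> small segment, no escalation
  pos <- seq_len(nrow(w)) == 2
  v <- verdicts_from(w, pos)
  out <- detect_with_escalation(corpus, v, "code_01",
                                pipeline_config(smoothing_radius = 0,
                                                threshold_fraction = 0.25))
  expect_equal(out$threshold_used, 1L)
  expect_equal(nrow(out$segments), 1)
  expect_lte(max(out$segments$word_count), 3000)
})

test_that("threshold monotonicity: higher thresholds select nested, smaller segments", {
  set.seed(5)
  wc <- sample(5:40, 120, replace = TRUE)
  smoothed <- oracle_smooth(sample(0:4, 120, replace = TRUE), 2)
  for (t1 in 1:3) {
    s1 <- group_segments(smoothed, t1, wc)
    s2 <- group_segments(smoothed, t1 + 1, wc)
    # containment: every higher-threshold segment lies inside a lower one
    for (j in seq_len(nrow(s2))) {
      inside <- any(s1$first_sentence <= s2$first_sentence[j] &
                      s2$last_sentence[j] <= s1$last_sentence)
      expect_true(inside)
    }
    expect_lte(sum(s2$word_count), sum(s1$word_count))
  }
})

test_that("radius 0 and threshold 1 reduce detection to the union of positive windows", {
  set.seed(21)
  wc <- sample(5:40, 150, replace = TRUE)
  corpus <- counted_corpus(wc)
  cfg <- pipeline_config(smoothing_radius = 0, threshold_fraction = 0.25,
                         segment_word_cap = 10^6)
  w <- make_windows(corpus, cfg)
  pos <- runif(nrow(w)) < 0.3
  v <- verdicts_from(w, pos)
  out <- detect_with_escalation(corpus, v, "code_01", cfg, windows = w)
  detected <- unlist(purrr::map2(out$segments$first_sentence,
                                 out$segments$last_sentence, seq))
  in_pos_window <- unique(unlist(purrr::map2(w$first_sentence[pos],
                                             w$last_sentence[pos], seq)))
  expect_setequal(detected, in_pos_window)
})

test_that("detection is a pure function of transcript, verdicts and config", {
  set.seed(3)
  wc <- sample(5:40, 80, replace = TRUE)
  corpus <- counted_corpus(wc)
  w <- make_windows(corpus, pipeline_config())
  v <- verdicts_from(w, runif(nrow(w)) < 0.4)
  a <- detect_with_escalation(corpus, v, "code_01", pipeline_config())
  b <- detect_with_escalation(corpus, v, "code_01", pipeline_config())
  expect_identical(a, b)
})
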