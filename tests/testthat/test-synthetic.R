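small_spec <- function(seed = 7, ...) {
  synthetic_spec(n_cases = 4, n_codes = 6, transcript_words = c(2000, 5000),
                 seed = seed, ...)
}

test_that("generation is a pure function of the spec", {
  a <- generate_corpus(small_spec())
  b <- generate_corpus(small_spec())
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$gold, b$gold)
  expect_identical(a$codebook, b$codebook)
  # byte-identical serialization
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_transcripts(a$corpus, fa)
  write_transcripts(b$corpus, fb)
  expect_identical(readLines(fa), readLines(fb))

  c2 <- generate_corpus(small_spec(seed = 8))
  expect_false(identical(a$corpus, c2$corpus))
})

test_that("corpus structure honours the spec invariants", {
  x <- generate_corpus(small_spec())
  expect_equal(dplyr::n_distinct(x$corpus$case_id), 4)
  expect_equal(nrow(x$codebook), 6)
  # offsets are running word sums within each case
  for (cid in unique(x$corpus$case_id)) {
    s <- x$corpus[x$corpus$case_id == cid, ]
    expect_equal(s$sentence_index, seq_len(nrow(s)) - 1L)
    expect_equal(s$start_offset, c(0L, cumsum(s$word_count)[-nrow(s)]))
  }
  # every planted sentence carries its code's keyword; filler carries none
  planted <- span_sentences(x$gold)
  for (i in seq_len(nrow(planted))) {
    sent <- x$corpus$text[x$corpus$case_id == planted$case_id[i]][planted$s[i] + 1]
    expect_true(grepl(x$keywords[[planted$code_id[i]]], sent, fixed = TRUE))
  }
  all_kw <- paste(unlist(x$keywords), collapse = "|")
  filler_idx <- dplyr::anti_join(
    x$corpus |> dplyr::select(case_id, s = sentence_index),
    planted |> dplyr::distinct(case_id, s),
    by = c("case_id", "s")
  )
  filler_text <- dplyr::inner_join(
    x$corpus, filler_idx,
    by = c("case_id", "sentence_index" = "s")
  )$text
  expect_false(any(grepl(all_kw, filler_text)))
  # fragments never overlap on the same sentences of a case
  overlap <- x$gold |>
    dplyr::group_by(case_id) |>
    dplyr::arrange(first_sentence, .by_group = TRUE) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::mutate(prev_last = dplyr::lag(last_sentence),
                  prev_first = dplyr::lag(first_sentence),
                  same_span = first_sentence == prev_first &
                    last_sentence == prev_last,
                  bad = !is.na(prev_last) & first_sentence <= prev_last &
                    !same_span)
  expect_false(any(overlap$bad, na.rm = TRUE))
})

test_that("planted fragment lengths have the stated mean and spread", {
  x <- generate_corpus(synthetic_spec(
    n_cases = 40, n_codes = 10, transcript_words = c(10000, 20000),
    code_prevalence = rep(2.6, 10), multi_code_rate = 0, seed = 19
  ))
  lens <- x$gold$word_count
  expect_gte(length(lens), 1000)
  se <- 190.57 / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 207.62), 3 * se + 1)  # +1 for integer rounding
  expect_lt(abs(stats::sd(lens) - 190.57) / 190.57, 0.15)
  expect_gte(min(lens), 10)
})

test_that("zero-prevalence codes stay in the codebook without gold fragments", {
  prev <- c(0, 1.5, 1.5, 1.5, 1.5, 1.5)
  x <- generate_corpus(small_spec(code_prevalence = prev))
  expect_false("code_01" %in% x$gold$code_id)
  expect_true("code_01" %in% x$codebook$code_id)
})

test_that("an infeasible prevalence profile is rejected with advice", {
  expect_error(
    generate_corpus(synthetic_spec(n_cases = 2, n_codes = 3,
                                   transcript_words = c(1000, 1200),
                                   code_prevalence = c(10, 10, 10), seed = 1)),
    class = "codewindow_prevalence_error"
  )
})

test_that("the noisy oracle hits its nominal error rates and is reproducible", {
  x <- generate_corpus(synthetic_spec(
    n_cases = 8, n_codes = 6, transcript_words = c(4000, 8000),
    code_prevalence = rep(0.8, 6), seed = 7
  ))
  # negative probes: windows of pure filler (no planted sentence)
  w <- make_windows(x$corpus, pipeline_config())
  wt <- window_text(x$corpus, w)
  planted <- span_sentences(x$gold)
  neg_idx <- purrr::pmap_lgl(
    wt[c("case_id", "first_sentence", "last_sentence")],
    function(case_id, first_sentence, last_sentence) {
      p <- planted[planted$case_id == case_id, ]
      !any(p$s >= first_sentence & p$s <= last_sentence)
    }
  )
  texts_neg <- wt$text[neg_idx]
  expect_gte(length(texts_neg), 300)
  code <- x$codebook[3, ]
  # positive probes: distinct filler texts with the code's keyword appended
  # (noise draws are keyed per text, so probes must be distinct strings)
  texts_pos <- paste(texts_neg, x$keywords[[code$code_id]])

  noisy <- make_noisy_oracle(x, fp_rate = 0.1, fn_rate = 0.02, seed = 5)
  v_pos <- parse_verdict(noisy$classify_batch(texts_pos, code))
  fn_hat <- mean(!v_pos)
  expect_lt(abs(fn_hat - 0.02),
            3 * sqrt(0.02 * 0.98 / length(texts_pos)) + 0.005)

  v_neg <- parse_verdict(noisy$classify_batch(texts_neg, code))
  fp_hat <- mean(as.logical(v_neg))
  expect_lt(abs(fp_hat - 0.1), 3 * sqrt(0.1 * 0.9 / length(texts_neg)))

  again <- make_noisy_oracle(x, fp_rate = 0.1, fn_rate = 0.02, seed = 5)
  expect_identical(noisy$classify_batch(texts_neg, code),
                   again$classify_batch(texts_neg, code))

  perfect <- make_noisy_oracle(x)
  expect_true(all(parse_verdict(perfect$classify_batch(texts_pos, code))))
  expect_false(any(parse_verdict(perfect$classify_batch(texts_neg, code))))
})

test_that("the perfect oracle recovers planted sentences end to end", {
  x <- generate_corpus(small_spec())
  cfg <- pipeline_config(smoothing_radius = 0, threshold_fraction = 0.25)
  run <- run_pipeline(x$corpus, x$codebook, make_noisy_oracle(x), cfg)
  expect_gte(planted_recall(run$segments, x$gold), 0.99)
  # precision floor: windows over-cover each fragment edge by < one window
  detected <- span_sentences(run$segments)
  hit <- dplyr::semi_join(detected, span_sentences(x$gold),
                          by = c("case_id", "code_id", "s"))
  precision <- nrow(hit) / nrow(detected)
  # each planted fragment contributes >= its own sentences; over-coverage is
  # bounded by ~2 window widths around each fragment
  mean_frag_sents <- mean(x$gold$last_sentence - x$gold$first_sentence + 1)
  max_extra_sents <- 2 * ceiling(300 / min(x$corpus$word_count))
  floor_bound <- mean_frag_sents / (mean_frag_sents + max_extra_sents)
  expect_gte(precision, floor_bound * 0.8)
})

test_that("raising the false-negative rate never raises planted recall", {
  recalls <- vapply(c(0, 0.3, 0.7), function(fn_rate) {
    mean(vapply(1:10, function(s) {
      x <- generate_corpus(synthetic_spec(
        n_cases = 2, n_codes = 3, transcript_words = c(1500, 2500),
        code_prevalence = rep(2, 3), seed = 100 + s
      ))
      ad <- make_noisy_oracle(x, fp_rate = 0, fn_rate = fn_rate, seed = s)
      run <- run_pipeline(x$corpus, x$codebook, ad,
                          pipeline_config(smoothing_radius = 0,
                                          threshold_fraction = 0.25))
      if (nrow(run$segments) == 0) 0 else planted_recall(run$segments, x$gold)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(recalls) <= 1e-9))
})
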