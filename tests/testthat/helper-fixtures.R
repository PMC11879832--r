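# Small in-code fixtures shared across test files.

# A corpus of n sentences of fixed word length for one case.
uniform_corpus <- function(n_sentences, words_per_sentence, case_id = "c1") {
  text <- vapply(seq_len(n_sentences), function(i) {
    paste0(paste(rep(sprintf("w%02d", i), words_per_sentence), collapse = " "), ".")
  }, character(1))
  wc <- rep(as.integer(words_per_sentence), n_sentences)
  tibble::tibble(
    case_id = case_id,
    speaker = NA_character_,
    sentence_index = seq_len(n_sentences) - 1L,
    text = text,
    word_count = wc,
    start_offset = c(0L, cumsum(wc)[-n_sentences])
  )
}

# A corpus with the given per-sentence word counts (content is filler).
counted_corpus <- function(word_counts, case_id = "c1") {
  text <- vapply(word_counts, function(k) {
    paste0(paste(rep("tok", k), collapse = " "), ".")
  }, character(1))
  wc <- as.integer(word_counts)
  tibble::tibble(
    case_id = case_id,
    speaker = NA_character_,
    sentence_index = seq_along(wc) - 1L,
    text = text,
    word_count = wc,
    start_offset = c(0L, cumsum(wc)[-length(wc)])
  )
}

# One-row confusion-count tibble.
cc <- function(tp, tn, fp, fn, code = "x") {
  tibble::tibble(code_id = code, tp = tp, tn = tn, fp = fp, fn = fn)
}

tiny_codebook <- function(n = 2) {
  tibble::tibble(
    code_id = sprintf("code_%02d", seq_len(n)),
    definition = sprintf("Mentions of theme %d, marked by 'kw%02d'", seq_len(n), seq_len(n)),
    positive_example = sprintf("They spoke about kw%02d at length.", seq_len(n)),
    negative_example = sprintf("Nothing of note happened that day %d.", seq_len(n))
  )
}

tiny_keywords <- function(n = 2) {
  stats::setNames(as.list(sprintf("kw%02d", seq_len(n))),
                  sprintf("code_%02d", seq_len(n)))
}

# Verdict tibble for one case from a logical vector (one code).
verdicts_from <- function(windows, positive, code_id = "code_01") {
  tibble::tibble(
    case_id = windows$case_id,
    window_id = windows$window_id,
    code_id = code_id,
    positive = positive
  )
}

expect_setequal_rows <- function(a, b) {
  expect_equal(dplyr::arrange(a, dplyr::across(dplyr::everything())),
               dplyr::arrange(b, dplyr::across(dplyr::everything())))
}

# Sentence-level recall/precision of detected segments against gold spans.
span_sentences <- function(df) {
  df |>
    dplyr::rowwise() |>
    dplyr::reframe(case_id = .data$case_id, code_id = .data$code_id,
                   s = seq(.data$first_sentence, .data$last_sentence))
}

planted_recall <- function(segments, gold) {
  planted <- span_sentences(gold)
  detected <- span_sentences(segments)
  nrow(dplyr::semi_join(planted, detected, by = c("case_id", "code_id", "s"))) /
    nrow(planted)
}
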