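#' Construct sliding windows over a corpus
#'
#' Windows are runs of consecutive sentences built by two rules: (1) a window
#' greedily extends sentence by sentence while its total word count stays
#' within `window_max_words`; (2) the next window starts at the first
#' sentence whose `start_offset` is at least `min_stride_words` beyond the
#' current window's start offset. Generation continues until a window's start
#' would fall beyond the final sentence, so every sentence belongs to at
#' least one window. A single sentence longer than the word cap becomes its
#' own over-cap window (reported via a warning); in that situation the next
#' start is clamped so no sentence is skipped.
#'
#' @param corpus Corpus tibble (`case_id`, `sentence_index`, `word_count`,
#'   `start_offset`, ...). Windows are built per case.
#' @param config A [pipeline_config()].
#' @return A tibble with columns `case_id`, `window_id` (1-based within
#'   case), `first_sentence`, `last_sentence` (0-based inclusive),
#'   `word_count`, `start_offset`.
#' @export
make_windows <- function(corpus, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  cap <- config$window_max_words
  stride <- config$min_stride_words
  over_cap <- 0L

  one_case <- function(df) {
    wc <- df$word_count
    off <- df$start_offset
    n <- length(wc)
    first <- integer(0); last <- integer(0)
    s <- 1L
    while (s <= n) {
      tot <- wc[s]
      e <- s
      while (e < n && tot + wc[e + 1L] <= cap) {
        e <- e + 1L
        tot <- tot + wc[e]
      }
      if (wc[s] > cap) over_cap <<- over_cap + 1L
      first <- c(first, s); last <- c(last, e)
      nxt <- which(off >= off[s] + stride)
      nxt <- if (length(nxt)) nxt[1] else n + 1L
      # never skip an uncovered sentence (possible only around an over-cap
      # sentence); coverage takes precedence over the stride rule
      s <- min(nxt, e + 1L)
    }
    tibble::tibble(
      window_id = seq_along(first),
      first_sentence = df$sentence_index[first],
      last_sentence = df$sentence_index[last],
      word_count = as.integer(off[last] + wc[last] - off[first]),
      start_offset = off[first]
    )
  }

  out <- corpus |>
    dplyr::group_by(.data$case_id) |>
    dplyr::group_modify(~ one_case(.x)) |>
    dplyr::ungroup()
  if (over_cap > 0) {
    rlang::warn(sprintf("%d single sentence(s) longer than the %d-word window cap became over-cap windows.",
                        over_cap, cap),
                class = "codewindow_overcap_window")
  }
  out
}

#' Paste the sentence text covered by each window
#'
#' @param corpus Corpus tibble.
#' @param windows Window tibble from [make_windows()].
#' @return `windows` with an added `text` column.
#' @export
window_text <- function(corpus, windows) {
  by_case <- split(corpus$text, corpus$case_id)
  windows |>
    dplyr::mutate(text = purrr::pmap_chr(
      list(.data$case_id, .data$first_sentence, .data$last_sentence),
      function(case_id, first, last) {
        paste(by_case[[case_id]][(first + 1L):(last + 1L)], collapse = " ")
      }
    ))
}

#' Design maximum number of windows covering one sentence
#'
#' The maximum overlap follows from the parameters alone (not from any
#' particular transcript): `ceiling(window_max_words / min_stride_words)`.
#' At the default 300/75 operating point this is 4.
#'
#' @param config A [pipeline_config()].
#' @return An integer.
#' @export
max_window_overlap <- function(config = pipeline_config()) {
  config <- as_pipeline_config(config)
  as.integer(ceiling(config$window_max_words / config$min_stride_words))
}

#' Initial peak-detection threshold
#'
#' `ceiling(threshold_fraction * max_window_overlap)`: 51% of the design
#' maximum overlap, rounded up to the next whole count. With the default
#' parameters (300, 75, 0.51) the maximum overlap is 4 and the threshold 3.
#'
#' @param config A [pipeline_config()].
#' @return An integer threshold (>= 1).
#' @export
initial_threshold <- function(config = pipeline_config()) {
  config <- as_pipeline_config(config)
  # epsilon guards against binary-representation artifacts (e.g. 0.2 * 5)
  as.integer(ceiling(config$threshold_fraction * max_window_overlap(config) - 1e-9))
}

#' Count positive-window coverage per sentence
#'
#' For one case and one code: `count[i]` is the number of positively
#' classified windows whose span contains sentence `i`. Sentences contained
#' in no positive window score 0.
#'
#' @param windows Window tibble for a single case.
#' @param verdicts Verdict tibble (`window_id`, `code_id`, `positive`) for
#'   the same case; must contain a verdict for every window of `code_id`.
#' @param code_id The code whose coverage is counted.
#' @param n_sentences Number of sentences in the transcript.
#' @return An integer vector of length `n_sentences` (index 1 is sentence 0).
#' @export
count_positive_coverage <- function(windows, verdicts, code_id, n_sentences) {
  v <- verdicts[verdicts$code_id == code_id, , drop = FALSE]
  missing <- setdiff(windows$window_id, v$window_id)
  if (length(missing) > 0) {
    abort_codewindow(
      paste0("Missing verdicts for code '", code_id, "' on window(s): ",
             paste(missing, collapse = ", ")),
      "codewindow_missing_verdict"
    )
  }
  pos <- dplyr::inner_join(windows, v[v$positive, c("window_id", "code_id")],
                           by = "window_id")
  counts <- integer(n_sentences)
  if (nrow(pos) > 0) {
    idx <- unlist(purrr::map2(pos$first_sentence + 1L, pos$last_sentence + 1L, seq))
    counts <- tabulate(idx, nbins = n_sentences)
  }
  as.integer(counts)
}

#' Moving-average smoothing with shrinking edges
#'
#' `smoothed[i]` is the mean of the raw counts over sentence indices
#' `[i - radius, i + radius]` intersected with the valid range — the
#' averaging window shrinks at transcript edges rather than padding with
#' zeros, so boundary peaks are not artificially suppressed. Radius 0 is the
#' identity.
#'
#' @param raw_counts Numeric vector of per-sentence counts.
#' @param radius Non-negative integer radius.
#' @return A numeric vector of the same length.
#' @examples
#' smooth_counts(c(0, 0, 4, 0, 0), radius = 1)
#' @export
smooth_counts <- function(raw_counts, radius) {
  if (radius < 0) abort_codewindow("`radius` must be >= 0.", "codewindow_config_error")
  n <- length(raw_counts)
  if (radius == 0 || n == 0) return(as.numeric(raw_counts))
  cs <- c(0, cumsum(raw_counts))
  i <- seq_len(n)
  lo <- pmax(1L, i - radius)
  hi <- pmin(n, i + radius)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Group above-threshold sentences into contiguous segments
#'
#' Maximal runs of consecutive sentences whose smoothed score is greater
#' than or equal to `threshold` become one detected segment each. The
#' selection rule is inclusive (`>=`) so that integer raw counts reaching
#' the threshold are selected.
#'
#' @param smoothed Numeric vector of smoothed per-sentence scores (index 1 is
#'   sentence 0).
#' @param threshold Numeric threshold (>= 1).
#' @param word_counts Integer vector of per-sentence word counts, same length.
#' @return A tibble with `first_sentence`, `last_sentence` (0-based
#'   inclusive) and `word_count`; zero rows when nothing is selected.
#' @export
group_segments <- function(smoothed, threshold, word_counts) {
  sel <- smoothed >= threshold
  if (!any(sel)) {
    return(tibble::tibble(first_sentence = integer(), last_sentence = integer(),
                          word_count = integer()))
  }
  r <- rle(sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(
    first_sentence = as.integer(starts[keep] - 1L),
    last_sentence = as.integer(ends[keep] - 1L),
    word_count = purrr::map2_int(starts[keep], ends[keep],
                                 ~ as.integer(sum(word_counts[.x:.y])))
  )
}

# Escalation core for one (case, code): group at increasing integer
# thresholds until every segment fits the word cap (a single over-cap
# sentence is allowed through, flagged) or the selection becomes empty.
# Terminates because selection is empty once threshold > max(smoothed).
escalate_one <- function(smoothed, word_counts, start_threshold, cap) {
  threshold <- as.integer(start_threshold)
  repeat {
    seg <- group_segments(smoothed, threshold, word_counts)
    over <- seg$word_count > cap
    singleton <- seg$first_sentence == seg$last_sentence
    if (!any(over & !singleton)) {
      return(list(
        segments = seg,
        threshold_used = threshold,
        dropped = nrow(seg) == 0 && threshold > start_threshold,
        overcap_singleton = any(over & singleton)
      ))
    }
    threshold <- threshold + 1L
  }
}

#' Detect coded segments with adaptive threshold escalation
#'
#' The full peak-detection path for one transcript and one code: positive
#' window coverage counts per sentence, moving-average smoothing, grouping of
#' above-threshold runs, and threshold escalation — starting at
#' [initial_threshold()] and incrementing by 1 — until the largest detected
#' segment is at most `segment_word_cap` words (the precondition for
#' single-prompt summarization). Escalating to an empty selection drops the
#' code for that transcript, with a warning.
#'
#' @param transcript Corpus tibble rows of a single case, in sentence order.
#' @param verdicts Verdict tibble for the same case (`window_id`, `code_id`,
#'   `positive`).
#' @param code_id Code to detect.
#' @param config A [pipeline_config()].
#' @param windows Optional precomputed window tibble for the case (avoids
#'   rebuilding windows in a loop over codes).
#' @return A list with `segments` (tibble: `case_id`, `code_id`,
#'   `first_sentence`, `last_sentence`, `word_count`, `threshold_used`),
#'   `threshold_used`, and `scores` (tibble: `sentence_index`, `raw_count`,
#'   `smoothed`).
#' @export
detect_with_escalation <- function(transcript, verdicts, code_id,
                                   config = pipeline_config(),
                                   windows = NULL) {
  config <- as_pipeline_config(config)
  case_id <- transcript$case_id[1]
  if (is.null(windows)) {
    windows <- make_windows(transcript, config)
  }
  counts <- count_positive_coverage(windows, verdicts, code_id, nrow(transcript))
  smoothed <- smooth_counts(counts, config$smoothing_radius)
  res <- escalate_one(smoothed, transcript$word_count,
                      initial_threshold(config), config$segment_word_cap)
  if (res$dropped) {
    rlang::warn(sprintf("Code '%s' dropped for case '%s': threshold escalated to emptiness.",
                        code_id, case_id),
                class = "codewindow_dropped_code")
  }
  if (res$overcap_singleton) {
    rlang::warn(sprintf("Code '%s', case '%s': a detected segment is a single sentence longer than the %d-word cap.",
                        code_id, case_id, config$segment_word_cap),
                class = "codewindow_overcap_segment")
  }
  seg <- res$segments
  segments <- tibble::tibble(
    case_id = rep(case_id, nrow(seg)),
    code_id = rep(code_id, nrow(seg)),
    first_sentence = seg$first_sentence,
    last_sentence = seg$last_sentence,
    word_count = seg$word_count,
    threshold_used = rep(res$threshold_used, nrow(seg))
  )
  list(
    segments = segments,
    threshold_used = res$threshold_used,
    scores = tibble::tibble(
      case_id = case_id,
      code_id = code_id,
      sentence_index = transcript$sentence_index,
      raw_count = counts,
      smoothed = smoothed
    )
  )
}

#' Detect segments for every case and code
#'
#' Runs [detect_with_escalation()] over all (case, code) combinations present
#' in the verdicts and binds the results.
#'
#' @param corpus Corpus tibble.
#' @param windows Window tibble from [make_windows()].
#' @param verdicts Verdict tibble (`case_id`, `window_id`, `code_id`,
#'   `positive`).
#' @param config A [pipeline_config()].
#' @param keep_scores Keep per-sentence score tables (can be large)?
#' @return A list with `segments` (one tibble over all cases and codes),
#'   `thresholds` (tibble: `case_id`, `code_id`, `threshold_used`,
#'   `n_segments`), and `scores` (tibble or `NULL`).
#' @export
detect_segments <- function(corpus, windows, verdicts,
                            config = pipeline_config(),
                            keep_scores = FALSE) {
  config <- as_pipeline_config(config)
  codes <- unique(verdicts$code_id)
  case_ids <- unique(corpus$case_id)
  corpus_split <- split(corpus, corpus$case_id)
  windows_split <- split(windows, windows$case_id)
  verdicts_split <- split(verdicts, verdicts$case_id)

  seg_list <- list(); thr_list <- list(); score_list <- list()
  for (cid in case_ids) {
    tr <- corpus_split[[cid]]
    wd <- windows_split[[cid]]
    vd <- verdicts_split[[cid]]
    for (code in codes) {
      res <- detect_with_escalation(tr, vd, code, config, windows = wd)
      seg_list[[length(seg_list) + 1L]] <- res$segments
      thr_list[[length(thr_list) + 1L]] <- tibble::tibble(
        case_id = cid, code_id = code,
        threshold_used = res$threshold_used,
        n_segments = nrow(res$segments)
      )
      if (keep_scores) score_list[[length(score_list) + 1L]] <- res$scores
    }
  }
  list(
    segments = dplyr::bind_rows(seg_list),
    thresholds = dplyr::bind_rows(thr_list),
    scores = if (keep_scores) dplyr::bind_rows(score_list) else NULL
  )
}

#' Write detected segments to disk
#'
#' Writes one line-delimited JSON record per segment and, alongside it, a CSV
#' summary of segment counts per code.
#'
#' @param segments Segment tibble from [detect_segments()].
#' @param path Output `.jsonl` path; the CSV summary gets suffix
#'   `_summary.csv`.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  lines <- purrr::pmap_chr(
    segments[c("case_id", "code_id", "first_sentence", "last_sentence",
               "word_count", "threshold_used")],
    function(case_id, code_id, first_sentence, last_sentence, word_count,
             threshold_used) {
      jsonlite::toJSON(list(case_id = case_id, code_id = code_id,
                            first_sentence = first_sentence,
                            last_sentence = last_sentence,
                            word_count = word_count,
                            threshold_used = threshold_used),
                       auto_unbox = TRUE)
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  summary <- segments |>
    dplyr::count(.data$code_id, name = "n_segments")
  readr::write_csv(summary, sub("\\.jsonl?$", "_summary.csv", path),
                   progress = FALSE)
  invisible(path)
}

#' Read detected segments from line-delimited JSON
#'
#' @param path Path written by [write_segments()].
#' @return A segment tibble.
#' @export
read_segments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- purrr::map(lines, jsonlite::fromJSON)
  tibble::tibble(
    case_id = purrr::map_chr(recs, "case_id"),
    code_id = purrr::map_chr(recs, "code_id"),
    first_sentence = purrr::map_int(recs, "first_sentence"),
    last_sentence = purrr::map_int(recs, "last_sentence"),
    word_count = purrr::map_int(recs, "word_count"),
    threshold_used = purrr::map_int(recs, "threshold_used")
  )
}
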