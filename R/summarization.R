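# Greedy feasibility: can `weights` (in order) be split into at most k
# contiguous batches each of total <= bound?
fits_in_k <- function(weights, k, bound) {
  if (any(weights > bound)) return(FALSE)
  batches <- 1L
  acc <- 0
  for (w in weights) {
    if (acc + w > bound) {
      batches <- batches + 1L
      acc <- w
    } else {
      acc <- acc + w
    }
  }
  batches <= k
}

# Minimal achievable maximum batch weight for an ordered split into k parts
# (binary search over candidate bounds).
min_max_weight <- function(weights, k) {
  lo <- max(weights)
  hi <- sum(weights)
  while (lo < hi) {
    mid <- floor((lo + hi) / 2)
    if (fits_in_k(weights, k, mid)) hi <- mid else lo <- mid + 1
  }
  lo
}

#' Split detected segments into summarization prompt batches
#'
#' If the pooled segments of one (case, code) fit the word budget they form a
#' single prompt; otherwise they are divided, in order, over the minimal
#' number of prompts such that a balanced split fits, with near-equal word
#' totals (the split minimizes the largest batch, then fills greedily under
#' that bound). Batches partition the segment list and preserve its order.
#'
#' @param segments Segment tibble for one (case, code), in order, with a
#'   `word_count` column.
#' @param budget_words Word budget of one prompt. Must be at least the
#'   largest single segment (guaranteed upstream by the detection word cap
#'   whenever `budget_words >= segment_word_cap`).
#' @return `segments` with an added integer `batch` column (1-based).
#' @export
batch_segments <- function(segments, budget_words) {
  n <- nrow(segments)
  if (n == 0) return(dplyr::mutate(segments, batch = integer(0)))
  w <- segments$word_count
  if (any(w > budget_words)) {
    abort_codewindow(
      paste0("A single segment (", max(w), " words) exceeds the prompt budget (",
             budget_words, "); the detection word cap was violated upstream."),
      "codewindow_batching_error"
    )
  }
  total <- sum(w)
  if (total <= budget_words) {
    return(dplyr::mutate(segments, batch = 1L))
  }
  k <- 2L
  while (!fits_in_k(w, k, budget_words)) k <- k + 1L
  bound <- min_max_weight(w, k)
  batch <- integer(n)
  b <- 1L; acc <- 0
  for (i in seq_len(n)) {
    if (acc + w[i] > bound) {
      b <- b + 1L
      acc <- 0
    }
    batch[i] <- b
    acc <- acc + w[i]
  }
  dplyr::mutate(segments, batch = batch)
}

#' Summarize the pooled segments of one (case, code)
#'
#' Each prompt batch is summarized separately; multi-batch outputs are
#' concatenated in batch order with a blank-line delimiter. A summarizer
#' failure yields a record with an empty summary and `failed = TRUE` — never
#' a silently dropped cell.
#'
#' @param case_id Case identifier.
#' @param code One-row codebook tibble.
#' @param batched Segment tibble for this (case, code) with `batch` and
#'   `text` columns (see [batch_segments()]).
#' @param summarizer A [summarizer()].
#' @return A one-row tibble: `case_id`, `code_id`, `summary`, `n_segments`,
#'   `n_batches`, `failed`, `source` (list column of segment spans).
#' @export
summarize_code <- function(case_id, code, batched, summarizer) {
  stopifnot(nrow(batched) > 0)
  batches <- split(batched, batched$batch)
  failed <- FALSE
  parts <- purrr::map_chr(batches, function(b) {
    tryCatch(
      summarizer$summarize(code$definition, b$text),
      error = function(e) {
        failed <<- TRUE
        ""
      }
    )
  })
  tibble::tibble(
    case_id = case_id,
    code_id = code$code_id,
    summary = if (failed) "" else paste(parts, collapse = "\n\n"),
    n_segments = nrow(batched),
    n_batches = length(batches),
    failed = failed,
    source = list(batched[c("first_sentence", "last_sentence", "batch")])
  )
}

#' Summarize all detected segments per case and code
#'
#' Pools each (case, code)'s detected segments, batches them under the prompt
#' budget, and summarizes with the given summarizer.
#'
#' @param segments Segment tibble from [detect_segments()].
#' @param corpus Corpus tibble (for segment text).
#' @param codebook Codebook tibble.
#' @param summarizer A [summarizer()].
#' @param budget_words Prompt word budget; defaults to the detection cap of
#'   the default [pipeline_config()].
#' @return A summary-record tibble, one row per (case, code) with segments.
#' @export
summarize_segments <- function(segments, corpus, codebook, summarizer,
                               budget_words = pipeline_config()$summary_budget_words) {
  if (nrow(segments) == 0) {
    return(tibble::tibble(case_id = character(), code_id = character(),
                          summary = character(), n_segments = integer(),
                          n_batches = integer(), failed = logical(),
                          source = list()))
  }
  by_case <- split(corpus$text, corpus$case_id)
  segments <- segments |>
    dplyr::mutate(text = purrr::pmap_chr(
      list(.data$case_id, .data$first_sentence, .data$last_sentence),
      function(case_id, first, last) {
        paste(by_case[[case_id]][(first + 1L):(last + 1L)], collapse = " ")
      }
    ))
  groups <- segments |>
    dplyr::group_by(.data$case_id, .data$code_id) |>
    dplyr::group_split()
  out <- purrr::map(groups, function(df) {
    code <- codebook[codebook$code_id == df$code_id[1], ]
    batched <- batch_segments(df, budget_words)
    summarize_code(df$case_id[1], code, batched, summarizer)
  })
  dplyr::bind_rows(out)
}

#' Assemble the case-by-code summary matrix
#'
#' The constant-comparative working matrix: interview cases in rows, codes in
#' columns, one summary per cell, with a cell present exactly when at least
#' one segment was detected for that (case, code).
#'
#' @param records Summary-record tibble from [summarize_segments()].
#' @param cases Character vector of all case ids (matrix rows).
#' @param codes Character vector of all code ids (matrix columns).
#' @return An object of class `"ccm_matrix"`: list with `records`, `cases`,
#'   `codes`.
#' @export
build_matrix <- function(records, cases, codes) {
  key <- paste(records$case_id, records$code_id, sep = ":")
  if (anyDuplicated(key)) {
    abort_codewindow(
      paste0("Duplicate (case, code) summary records: ",
             paste(unique(key[duplicated(key)]), collapse = ", ")),
      "codewindow_matrix_error"
    )
  }
  stray <- records[!(records$case_id %in% cases) | !(records$code_id %in% codes), ]
  if (nrow(stray) > 0) {
    abort_codewindow("Summary records outside the declared case/code universe.",
                     "codewindow_matrix_error")
  }
  structure(list(records = records, cases = cases, codes = codes),
            class = "ccm_matrix")
}

#' @export
print.ccm_matrix <- function(x, ...) {
  cat(sprintf("<ccm_matrix: %d cases x %d codes, %d filled cells (%.0f%%)>\n",
              length(x$cases), length(x$codes), nrow(x$records),
              100 * nrow(x$records) / (length(x$cases) * length(x$codes))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Long-form view of a summary matrix
#'
#' @param x A `"ccm_matrix"`.
#' @param ... Unused.
#' @return A tibble with one row per filled cell: `case_id`, `code_id`,
#'   `summary`, `n_source_segments`.
#' @method tidy ccm_matrix
#' @export
tidy.ccm_matrix <- function(x, ...) {
  tibble::tibble(
    case_id = x$records$case_id,
    code_id = x$records$code_id,
    summary = x$records$summary,
    n_source_segments = x$records$n_segments
  )
}

#' Matrix-level summary of a summary matrix
#'
#' @param x A `"ccm_matrix"`.
#' @param ... Unused.
#' @return A one-row tibble: `n_cases`, `n_codes`, `n_cells`, `fill_rate`,
#'   `n_failed`.
#' @method glance ccm_matrix
#' @export
glance.ccm_matrix <- function(x, ...) {
  tibble::tibble(
    n_cases = length(x$cases),
    n_codes = length(x$codes),
    n_cells = nrow(x$records),
    fill_rate = nrow(x$records) / (length(x$cases) * length(x$codes)),
    n_failed = sum(x$records$failed)
  )
}

#' Write a summary matrix as CSV
#'
#' Writes the wide cases-by-codes grid (empty string for empty cells) and a
#' long-form companion (`case_id`, `code_id`, `summary`,
#' `n_source_segments`).
#'
#' @param x A `"ccm_matrix"`.
#' @param path Output CSV path for the wide grid; the long form gets suffix
#'   `_long.csv`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  long <- tidy(x)
  wide <- tidyr::crossing(case_id = x$cases, code_id = x$codes) |>
    dplyr::left_join(long[c("case_id", "code_id", "summary")],
                     by = c("case_id", "code_id")) |>
    dplyr::mutate(summary = dplyr::coalesce(.data$summary, "")) |>
    tidyr::pivot_wider(names_from = "code_id", values_from = "summary")
  wide <- wide[order(match(wide$case_id, x$cases)), ]
  readr::write_csv(wide, path, progress = FALSE)
  readr::write_csv(long, sub("\\.csv$", "_long.csv", path), progress = FALSE)
  invisible(path)
}

#' Read human summary ratings
#'
#' Ratings are produced by human raters and ingested as data; each record is
#' one rater's verdict on one (case, code) summary, with rating labels
#' `good`, `adequate` or `poor`.
#'
#' @param path CSV with columns `case_id`, `code_id`, `rater`, `rating`.
#' @return A ratings tibble.
#' @export
read_ratings <- function(path) {
  r <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_ratings(r)
}

validate_ratings <- function(ratings) {
  needed <- c("case_id", "code_id", "rater", "rating")
  missing_cols <- setdiff(needed, names(ratings))
  if (length(missing_cols) > 0) {
    abort_codewindow(paste0("Ratings are missing columns: ",
                            paste(missing_cols, collapse = ", ")),
                     "codewindow_rating_error")
  }
  bad <- setdiff(unique(ratings$rating), c("good", "adequate", "poor"))
  if (length(bad) > 0) {
    abort_codewindow(paste0("Invalid rating labels: ", paste(bad, collapse = ", ")),
                     "codewindow_rating_error")
  }
  key <- paste(ratings$case_id, ratings$code_id, ratings$rater)
  if (anyDuplicated(key)) {
    abort_codewindow("More than one rating per (case, code, rater).",
                     "codewindow_rating_error")
  }
  tibble::as_tibble(ratings)
}
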