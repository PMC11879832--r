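# Obtain verdicts for a vector of target texts under one code, honouring the
# adapter contract: scalar path builds the full few-shot sequence per text;
# the batch fast path is used when the adapter provides one. A failing scalar
# call is retried once, then counted as a negative verdict (default-False)
# with a warning.
adapter_verdicts <- function(adapter, code, texts) {
  if (length(texts) == 0) return(logical(0))
  if (!is.null(adapter$classify_batch)) {
    responses <- adapter$classify_batch(texts, code)
  } else {
    responses <- vapply(texts, function(txt) {
      seq <- build_fewshot_sequence(code, txt)
      tryCatch(
        adapter$classify(seq),
        error = function(e) {
          tryCatch(adapter$classify(seq), error = function(e2) {
            rlang::warn(paste0("Classifier failed twice for code '", code$code_id,
                               "'; counting a negative verdict."),
                        class = "codewindow_adapter_failure")
            "False."
          })
        }
      )
    }, character(1), USE.NAMES = FALSE)
  }
  v <- parse_verdict(responses)
  n_bad <- attr(v, "n_unparseable")
  if (n_bad > 0) {
    rlang::inform(sprintf("%d unparseable response(s) for code '%s' defaulted to False.",
                          n_bad, code$code_id),
                  class = "codewindow_unparseable_tally")
  }
  as.logical(v)
}

#' Build the balanced fragment dataset for binary classification
#'
#' For each code, all its gold fragments become positive items and
#' `negatives_per_positive` times as many negatives are sampled uniformly
#' (seeded) from fragments that do not carry that code. Fragments whose text
#' equals one of the code's few-shot examples are excluded on both sides.
#' Per-code sampling uses a seed derived from (`seed`, code position), so a
#' given seed reproduces the identical item list.
#'
#' @param gold Gold-fragment tibble with a `text` column (see
#'   [gold_with_text()]).
#' @param codebook Codebook tibble.
#' @param negatives_per_positive Integer ratio of sampled negatives to
#'   positives (default 1, a balanced set).
#' @param seed Integer seed.
#' @return A tibble of items: `code_id`, `case_id`, `fragment_id`, `text`,
#'   `gold` (logical).
#' @export
build_level1_dataset <- function(gold, codebook, negatives_per_positive = 1,
                                 seed = 1L) {
  stopifnot(negatives_per_positive >= 0)
  gold <- gold |>
    dplyr::mutate(fragment_id = paste(.data$case_id, .data$first_sentence,
                                      .data$last_sentence, sep = ":"))
  # one row per distinct fragment, with the set of codes it carries
  frags <- gold |>
    dplyr::group_by(.data$fragment_id, .data$case_id, .data$text) |>
    dplyr::summarise(codes = list(unique(.data$code_id)), .groups = "drop")

  out <- purrr::imap(
    stats::setNames(seq_len(nrow(codebook)), codebook$code_id),
    function(i, code_id) {
      code <- codebook[i, ]
      carries <- purrr::map_lgl(frags$codes, ~ code_id %in% .x)
      is_example <- frags$text %in% c(code$positive_example, code$negative_example)
      pos <- frags[carries & !is_example, ]
      neg_pool <- frags[!carries & !is_example, ]
      n_neg <- nrow(pos) * negatives_per_positive
      if (n_neg > nrow(neg_pool)) {
        abort_codewindow(
          paste0("Insufficient negative pool for code '", code_id, "': need ",
                 n_neg, ", have ", nrow(neg_pool), "."),
          "codewindow_sampling_error"
        )
      }
      code_seed <- (as.numeric(seed) * 1000003 + i) %% 2147483647
      neg <- withr::with_seed(as.integer(code_seed), {
        neg_pool[sample.int(nrow(neg_pool), n_neg), ]
      })
      dplyr::bind_rows(
        tibble::tibble(code_id = code_id, case_id = pos$case_id,
                       fragment_id = pos$fragment_id, text = pos$text,
                       gold = TRUE),
        tibble::tibble(code_id = code_id, case_id = neg$case_id,
                       fragment_id = neg$fragment_id, text = neg$text,
                       gold = FALSE)
      )
    }
  )
  dplyr::bind_rows(out)
}

#' Run binary fragment classification and tally confusion counts
#'
#' Each item is classified for its code through the adapter (via the few-shot
#' message protocol) and compared to its gold label: positive gold and
#' positive verdict is a true positive, negative/negative a true negative,
#' negative gold with a positive verdict a false positive, positive gold with
#' a negative verdict a false negative.
#'
#' @param items Item tibble from [build_level1_dataset()].
#' @param codebook Codebook tibble.
#' @param adapter A [classifier_adapter()].
#' @return A tibble of per-code confusion counts: `code_id`, `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
classify_level1 <- function(items, codebook, adapter) {
  by_code <- split(items, items$code_id)
  out <- purrr::map(by_code, function(df) {
    code <- codebook[codebook$code_id == df$code_id[1], ]
    verdict <- adapter_verdicts(adapter, code, df$text)
    tibble::tibble(
      code_id = df$code_id[1],
      tp = sum(df$gold & verdict),
      tn = sum(!df$gold & !verdict),
      fp = sum(!df$gold & verdict),
      fn = sum(df$gold & !verdict)
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(match(.data$code_id, codebook$code_id))
}

#' Classify every sliding window against every code
#'
#' The Level-2 scan: the same few-shot classification prompt, applied to each
#' window's text for each code in the codebook. Verdicts can be cached to a
#' line-delimited JSON file keyed by (case, window span, code) so expensive
#' backends are resumable: cached keys are never re-queried.
#'
#' @param corpus Corpus tibble.
#' @param windows Window tibble from [make_windows()]; built from `corpus`
#'   when `NULL`.
#' @param codebook Codebook tibble (may have zero rows, giving zero
#'   verdicts).
#' @param adapter A [classifier_adapter()].
#' @param config A [pipeline_config()].
#' @param cache_path Optional verdict cache file (`.jsonl`).
#' @return A verdict tibble: `case_id`, `window_id`, `code_id`, `positive`.
#' @export
classify_windows <- function(corpus, codebook, adapter,
                             config = pipeline_config(),
                             windows = NULL, cache_path = NULL) {
  config <- as_pipeline_config(config)
  if (is.null(windows)) windows <- make_windows(corpus, config)
  if (nrow(codebook) == 0) {
    return(tibble::tibble(case_id = character(), window_id = integer(),
                          code_id = character(), positive = logical()))
  }
  wt <- window_text(corpus, windows)
  grid <- tidyr::crossing(wt[c("case_id", "window_id", "first_sentence",
                               "last_sentence", "text")],
                          code_id = codebook$code_id) |>
    dplyr::mutate(key = paste(.data$case_id, .data$first_sentence,
                              .data$last_sentence, .data$code_id, sep = ":"))

  cached <- NULL
  if (!is.null(cache_path) && file.exists(cache_path)) {
    cached <- read_verdict_cache(cache_path)
  }
  todo <- grid
  if (!is.null(cached) && nrow(cached) > 0) {
    todo <- grid[!(grid$key %in% cached$key), ]
  }

  new_verdicts <- NULL
  if (nrow(todo) > 0) {
    per_code <- split(todo, todo$code_id)
    new_verdicts <- dplyr::bind_rows(purrr::map(per_code, function(df) {
      code <- codebook[codebook$code_id == df$code_id[1], ]
      df$positive <- adapter_verdicts(adapter, code, df$text)
      df[c("case_id", "window_id", "code_id", "key", "positive")]
    }))
  }

  all_v <- dplyr::bind_rows(
    if (!is.null(cached)) dplyr::semi_join(cached, grid, by = "key") else NULL,
    new_verdicts
  )
  if (!is.null(cache_path) && !is.null(new_verdicts) && nrow(new_verdicts) > 0) {
    append_verdict_cache(new_verdicts, cache_path)
  }
  grid |>
    dplyr::select("case_id", "window_id", "code_id", "key") |>
    dplyr::left_join(all_v[c("key", "positive")], by = "key") |>
    dplyr::select(-"key")
}

read_verdict_cache <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) return(NULL)
  recs <- purrr::map(lines, jsonlite::fromJSON)
  tibble::tibble(
    case_id = purrr::map_chr(recs, "case_id"),
    window_id = purrr::map_int(recs, "window_id"),
    code_id = purrr::map_chr(recs, "code_id"),
    key = purrr::map_chr(recs, "key"),
    positive = purrr::map_lgl(recs, "positive")
  )
}

append_verdict_cache <- function(verdicts, path) {
  lines <- purrr::pmap_chr(
    verdicts[c("case_id", "window_id", "code_id", "key", "positive")],
    function(case_id, window_id, code_id, key, positive) {
      jsonlite::toJSON(list(case_id = case_id, window_id = window_id,
                            code_id = code_id, key = key, positive = positive),
                       auto_unbox = TRUE)
    }
  )
  con <- file(path, open = "a", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
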