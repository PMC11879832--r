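#' Split raw text into sentences with word bookkeeping
#'
#' Sentences are the atomic unit of the sliding window: every window, peak
#' count and detected segment is expressed in sentence indices. Text is split
#' at `.`, `!` or `?` (possibly repeated) followed by whitespace or end of
#' string; the terminator stays attached to its sentence. Any residual tail
#' without a terminator becomes a final sentence. Protected abbreviations
#' (e.g. `"e.g."`) are shielded from splitting.
#'
#' Coordinates are 0-based sentence indices; `start_offset` is the cumulative
#' word count of all preceding sentences, so `start_offset + word_count` of
#' the last sentence equals the transcript's total words.
#'
#' @param raw_text A single string.
#' @param abbreviations Character vector of dot-terminated abbreviations that
#'   must not end a sentence.
#' @return A tibble with columns `sentence_index` (0-based), `text`,
#'   `word_count`, `start_offset`.
#' @examples
#' split_sentences("Hij fietste weg. Niemand zag het.")
#' @export
split_sentences <- function(raw_text, abbreviations = character()) {
  if (length(raw_text) != 1 || is.na(raw_text) || !nzchar(stringr::str_trim(raw_text))) {
    abort_codewindow("Cannot split an empty or whitespace-only transcript.",
                     "codewindow_empty_transcript")
  }
  txt <- raw_text
  # shield protected abbreviations by swapping their dots for a placeholder
  placeholder <- "\x01"
  for (ab in abbreviations) {
    txt <- gsub(ab, gsub(".", placeholder, ab, fixed = TRUE), txt, fixed = TRUE)
  }
  # break after terminator runs followed by whitespace; keep terminator
  pieces <- strsplit(gsub("([.!?]+)\\s+", "\\1\x02", txt), "\x02", fixed = TRUE)[[1]]
  pieces <- gsub(placeholder, ".", pieces, fixed = TRUE)
  pieces <- stringr::str_trim(pieces)
  pieces <- pieces[nzchar(pieces)]
  wc <- count_words(pieces)
  tibble::tibble(
    sentence_index = seq_along(pieces) - 1L,
    text = pieces,
    word_count = wc,
    start_offset = c(0L, cumsum(wc)[-length(wc)])
  )
}

# Rebuild word offsets after concatenating sentence tables (per case).
reindex_sentences <- function(sentences) {
  sentences |>
    dplyr::group_by(.data$case_id) |>
    dplyr::mutate(
      sentence_index = dplyr::row_number() - 1L,
      start_offset = c(0L, cumsum(.data$word_count)[-dplyr::n()])
    ) |>
    dplyr::ungroup()
}

#' Read interview transcripts
#'
#' Reads either a line-delimited JSON file (one utterance record per line
#' with keys `case_id`, `speaker`, `text`) or a directory of UTF-8 plain-text
#' files, one transcript per file (the file name minus extension is the case
#' id). Utterances are split into sentences with [split_sentences()]; record
#' order is preserved within each case, and cases appear in file order.
#' Unknown record fields are ignored with a warning; a duplicated explicit
#' `record_index` within a case is a format error.
#'
#' @param path Path to a `.jsonl` file or a directory of `.txt` files.
#' @param abbreviations Passed to [split_sentences()].
#' @return A corpus tibble: `case_id`, `speaker` (NA for plain text),
#'   `sentence_index`, `text`, `word_count`, `start_offset`.
#' @seealso [write_transcripts()] for the inverse.
#' @export
read_transcripts <- function(path, abbreviations = character()) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
    out <- purrr::map(files, function(f) {
      raw <- paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = " ")
      split_sentences(raw, abbreviations) |>
        dplyr::mutate(case_id = sub("\\.txt$", "", basename(f)),
                      speaker = NA_character_)
    })
    return(dplyr::bind_rows(out) |>
             dplyr::select("case_id", "speaker", "sentence_index",
                           "text", "word_count", "start_offset"))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(case_id = character(), speaker = character(),
                          sentence_index = integer(), text = character(),
                          word_count = integer(), start_offset = integer()))
  }
  recs <- purrr::map(lines, jsonlite::fromJSON)
  known <- c("case_id", "speaker", "text", "record_index")
  extra <- setdiff(unique(unlist(purrr::map(recs, names))), known)
  if (length(extra) > 0) {
    rlang::warn(paste0("Ignoring unknown transcript record fields: ",
                       paste(extra, collapse = ", ")),
                class = "codewindow_unknown_fields")
  }
  records <- tibble::tibble(
    case_id = purrr::map_chr(recs, ~ as.character(.x$case_id)),
    speaker = purrr::map_chr(recs, ~ as.character(.x$speaker %||% NA_character_)),
    text = purrr::map_chr(recs, ~ as.character(.x$text)),
    record_index = purrr::map_int(recs, ~ as.integer(.x$record_index %||% NA_integer_))
  )
  if (any(!is.na(records$record_index))) {
    dup <- records |>
      dplyr::filter(!is.na(.data$record_index)) |>
      dplyr::count(.data$case_id, .data$record_index) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort_codewindow(
        paste0("Duplicate (case_id, record_index) pairs: ",
               paste(dup$case_id, dup$record_index, sep = ":", collapse = ", ")),
        "codewindow_format_error"
      )
    }
  }
  # group per case preserving record order; cases ordered by first appearance
  case_order <- unique(records$case_id)
  sentences <- records |>
    dplyr::mutate(.rec = dplyr::row_number()) |>
    dplyr::arrange(match(.data$case_id, case_order), .data$.rec) |>
    dplyr::mutate(parts = purrr::map(.data$text, split_sentences, abbreviations)) |>
    dplyr::select("case_id", "speaker", "parts") |>
    tidyr::unnest("parts") |>
    dplyr::select("case_id", "speaker", "text", "word_count")
  reindex_sentences(sentences) |>
    dplyr::select("case_id", "speaker", "sentence_index",
                  "text", "word_count", "start_offset")
}

#' Write a corpus as line-delimited JSON utterance records
#'
#' One record per sentence with keys `case_id`, `speaker`, `text`, so that
#' [read_transcripts()] reproduces the sentence sequence and case
#' partitioning exactly.
#'
#' @param corpus A corpus tibble as returned by [read_transcripts()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(corpus, path) {
  lines <- purrr::pmap_chr(
    list(corpus$case_id,
         corpus$speaker %||% rep(NA_character_, nrow(corpus)),
         corpus$text),
    function(case_id, speaker, text) {
      jsonlite::toJSON(list(case_id = case_id, speaker = speaker, text = text),
                       auto_unbox = TRUE, null = "null", na = "null")
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Per-case transcript summaries
#'
#' @param corpus A corpus tibble.
#' @return A tibble with `case_id`, `n_sentences`, `total_words`.
#' @export
transcript_stats <- function(corpus) {
  corpus |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(n_sentences = dplyr::n(),
                     total_words = sum(.data$word_count),
                     .groups = "drop")
}

#' Read a deductive codebook
#'
#' A codebook row is one code: an identifier, a prose topic definition (the
#' text actually embedded in the classification prompt), and one positive and
#' one negative example fragment used as the few-shot demonstrations.
#'
#' @param path CSV or JSON file with columns/fields `code_id`, `definition`,
#'   `positive_example`, `negative_example`. Extra columns are ignored.
#' @return A codebook tibble with the four columns above.
#' @export
read_codebook <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    cb <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    cb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_codebook(cb)
}

#' Validate a codebook tibble
#'
#' @param codebook A data frame with columns `code_id`, `definition`,
#'   `positive_example`, `negative_example`.
#' @return The validated codebook as a tibble (extra columns dropped).
#' @export
validate_codebook <- function(codebook) {
  needed <- c("code_id", "definition", "positive_example", "negative_example")
  missing_cols <- setdiff(needed, names(codebook))
  if (length(missing_cols) > 0) {
    abort_codewindow(paste0("Codebook is missing columns: ",
                            paste(missing_cols, collapse = ", ")),
                     "codewindow_codebook_error")
  }
  cb <- tibble::as_tibble(codebook)[needed]
  dup <- cb$code_id[duplicated(cb$code_id)]
  if (length(dup) > 0) {
    abort_codewindow(paste0("Duplicated code_id: ", paste(unique(dup), collapse = ", ")),
                     "codewindow_codebook_error")
  }
  bad <- cb |>
    dplyr::filter(is.na(.data$definition) | !nzchar(.data$definition) |
                    is.na(.data$positive_example) | !nzchar(.data$positive_example) |
                    is.na(.data$negative_example) | !nzchar(.data$negative_example) |
                    .data$positive_example == .data$negative_example)
  if (nrow(bad) > 0) {
    abort_codewindow(
      paste0("Codes with missing/invalid definition or examples: ",
             paste(bad$code_id, collapse = ", ")),
      "codewindow_codebook_error"
    )
  }
  cb
}

#' Read gold-standard coded fragments
#'
#' @param path CSV with columns `case_id`, `code_id`, `first_sentence`,
#'   `last_sentence` (0-based inclusive sentence spans).
#' @return A tibble of gold fragments.
#' @export
read_gold <- function(path) {
  g <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         case_id = readr::col_character(),
                         code_id = readr::col_character(),
                         first_sentence = readr::col_integer(),
                         last_sentence = readr::col_integer()
                       ))
  tibble::as_tibble(g)
}

#' Write gold fragments as CSV
#'
#' @param gold Gold-fragment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  readr::write_csv(gold[c("case_id", "code_id", "first_sentence", "last_sentence")],
                   path, progress = FALSE)
  invisible(path)
}

#' Attach fragment text to gold annotations
#'
#' Resolves each gold span against the corpus and pastes the spanned
#' sentences into a `text` column. Spans must lie within their transcript.
#'
#' @param gold Gold-fragment tibble (`case_id`, `code_id`, `first_sentence`,
#'   `last_sentence`).
#' @param corpus Corpus tibble.
#' @return `gold` with added `text` and `word_count` columns.
#' @export
gold_with_text <- function(gold, corpus) {
  stats <- transcript_stats(corpus)
  g <- dplyr::left_join(gold, stats, by = "case_id")
  bad <- g |>
    dplyr::filter(is.na(.data$n_sentences) |
                    .data$first_sentence < 0 |
                    .data$first_sentence > .data$last_sentence |
                    .data$last_sentence >= .data$n_sentences)
  if (nrow(bad) > 0) {
    abort_codewindow(
      paste0("Gold spans outside their transcript for cases: ",
             paste(unique(bad$case_id), collapse = ", ")),
      "codewindow_gold_error"
    )
  }
  by_case <- split(corpus, corpus$case_id)
  g |>
    dplyr::mutate(
      text = purrr::pmap_chr(
        list(.data$case_id, .data$first_sentence, .data$last_sentence),
        function(case_id, first, last) {
          s <- by_case[[case_id]]
          paste(s$text[(first + 1L):(last + 1L)], collapse = " ")
        }
      ),
      word_count = count_words(.data$text)
    ) |>
    dplyr::select(-"n_sentences", -"total_words")
}
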