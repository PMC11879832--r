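# The chat protocol used for every classification call. The system prompt
# carries the default-False contract; the user template embeds the code's
# prose definition (not its short name) and the text under scrutiny.
classification_system_prompt <- paste(
  "You are a helpful assistant. Your task is to determine whether a given",
  "topic is explicitly mentioned in segments of interview transcripts",
  "between interviewers and relatives of suicide victims. Respond with",
  "'True' or 'False,' initially assuming 'False' unless the text explicitly",
  "proves otherwise."
)

classification_user_template <-
  "Could you please tell me if the topic '%s' is mentioned in the interview transcript: '%s'?"

summarization_system_prompt <- "You are a helpful assistant."

summarization_user_template <- paste(
  "Summarize all information relevant to the topic '%s' in the following",
  "text, citing the original wording where possible: '%s'"
)

new_message <- function(role, content) {
  stopifnot(role %in% c("system", "user", "assistant"))
  tibble::tibble(role = role, content = content)
}

render_user_prompt <- function(definition, text) {
  sprintf(classification_user_template, definition, text)
}

#' Build the few-shot classification message sequence for one code
#'
#' Constructs the six-message chat sequence used for every binary
#' classification call: a system message stating the default-False contract,
#' then two demonstration rounds — the code's positive example answered
#' `"True."` and its negative example answered `"False."` — and finally the
#' target text as an open user turn. Fragments are embedded verbatim (no
#' escaping of inner quotes). The construction is deterministic: identical
#' inputs give byte-identical sequences.
#'
#' @param code A one-row codebook tibble (or list) with `definition`,
#'   `positive_example`, `negative_example`.
#' @param target_text The text to classify. Must differ from both few-shot
#'   examples: example fragments are excluded from evaluation data, and
#'   classifying one would leak a demonstration into the query.
#' @return A tibble with columns `role`, `content` (6 rows).
#' @examples
#' cb <- tibble::tibble(code_id = "c1", definition = "use of substances",
#'                      positive_example = "He drank heavily.",
#'                      negative_example = "She took the train.")
#' build_fewshot_sequence(cb, "They found empty bottles.")
#' @export
build_fewshot_sequence <- function(code, target_text) {
  if (length(target_text) != 1 || is.na(target_text) || !nzchar(target_text)) {
    abort_codewindow("`target_text` must be a non-empty string.",
                     "codewindow_prompt_error")
  }
  if (identical(target_text, code$positive_example) ||
      identical(target_text, code$negative_example)) {
    abort_codewindow(
      paste0("Target text equals a few-shot example of code '",
             code$code_id %||% "?",
             "'; example fragments must be excluded from evaluation data."),
      "codewindow_leakage_error"
    )
  }
  dplyr::bind_rows(
    new_message("system", classification_system_prompt),
    new_message("user", render_user_prompt(code$definition, code$positive_example)),
    new_message("assistant", "True."),
    new_message("user", render_user_prompt(code$definition, code$negative_example)),
    new_message("assistant", "False."),
    new_message("user", render_user_prompt(code$definition, target_text))
  )
}

#' Build the summarization message sequence for one prompt batch
#'
#' @param code A one-row codebook tibble (or list) with `definition`.
#' @param batch_text Concatenated text of the segments in one batch.
#' @return A tibble with columns `role`, `content` (2 rows).
#' @export
build_summary_sequence <- function(code, batch_text) {
  dplyr::bind_rows(
    new_message("system", summarization_system_prompt),
    new_message("user", sprintf(summarization_user_template,
                                code$definition, batch_text))
  )
}

#' Parse classifier responses into boolean verdicts
#'
#' Implements the default-False contract: a response is positive if and only
#' if its first alphabetic token, lower-cased and stripped of punctuation, is
#' `"true"`. Everything else — including empty or free-form responses — is a
#' negative verdict. Responses whose first alphabetic token is neither
#' `"true"` nor `"false"` (or that contain no alphabetic token) are counted
#' as unparseable; the count is attached as attribute `"n_unparseable"` and
#' the per-response flags as attribute `"unparseable"`.
#'
#' @param response_text Character vector of raw classifier responses.
#' @return A logical vector of verdicts with attributes `"unparseable"`
#'   (logical vector) and `"n_unparseable"` (integer).
#' @examples
#' parse_verdict(c("True.", "false, because ...", ""))
#' @export
parse_verdict <- function(response_text) {
  first_tok <- stringr::str_match(response_text %||% character(),
                                  "([A-Za-z]+)")[, 2]
  first_tok <- tolower(first_tok)
  verdict <- !is.na(first_tok) & first_tok == "true"
  unparseable <- is.na(first_tok) | !(first_tok %in% c("true", "false"))
  structure(verdict,
            unparseable = unparseable,
            n_unparseable = sum(unparseable))
}
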