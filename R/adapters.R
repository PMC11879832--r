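#' Create a classifier adapter
#'
#' An adapter wraps any binary topic classifier behind two contracts:
#' `classify(messages)` takes one chat message tibble (as built by
#' [build_fewshot_sequence()]) and returns the raw response string of the
#' backend; optionally `classify_batch(texts, code)` takes a character vector
#' of target texts plus one codebook row and returns a character vector of
#' responses — a fast path that orchestration uses when present (its results
#' must match the scalar path; the test-suite property checks this for the
#' bundled mocks). A deterministic adapter returns byte-identical responses
#' for identical inputs.
#'
#' @param name Adapter name.
#' @param classify Function `(messages) -> character(1)`.
#' @param classify_batch Optional function `(texts, code) -> character`.
#' @param deterministic Logical flag.
#' @return An object of class `"classifier_adapter"`.
#' @export
classifier_adapter <- function(name, classify, classify_batch = NULL,
                               deterministic = TRUE) {
  structure(
    list(name = name, classify = classify, classify_batch = classify_batch,
         deterministic = isTRUE(deterministic)),
    class = "classifier_adapter"
  )
}

#' @export
print.classifier_adapter <- function(x, ...) {
  cat(sprintf("<classifier_adapter: %s%s%s>\n", x$name,
              if (x$deterministic) ", deterministic" else "",
              if (!is.null(x$classify_batch)) ", batched" else ""))
  invisible(x)
}

# Pull the target text back out of the final user message. The user template
# has fixed flanking markers, so the embedded fragment is the substring
# between them even when it contains quotes.
extract_target_text <- function(user_content) {
  marker <- "' is mentioned in the interview transcript: '"
  start <- regexpr(marker, user_content, fixed = TRUE)
  out <- substr(user_content, start + attr(start, "match.length"),
                nchar(user_content) - 2L)  # strip trailing '?
  out[start < 0] <- NA_character_
  out
}

extract_definition <- function(user_content) {
  pre <- "Could you please tell me if the topic '"
  marker <- "' is mentioned in the interview transcript: '"
  start <- regexpr(marker, user_content, fixed = TRUE)
  out <- substr(user_content, nchar(pre) + 1L, start - 1L)
  out[start < 0] <- NA_character_
  out
}

#' Deterministic keyword mock classifier
#'
#' A test double standing in for a chat-completion backend. With both noise
#' rates zero, the verdict is exactly "any of the code's keywords occurs in
#' the target text". Noise flips negatives to positives with probability
#' `fp_rate` and positives to negatives with probability `fn_rate`; each flip
#' is drawn from a generator keyed by (target text, code, seed), so answers
#' are reproducible regardless of call order and the global RNG is never
#' touched.
#'
#' The adapter recovers the code from the prose definition embedded in the
#' final user message, which is why it needs the codebook.
#'
#' @param codebook Codebook tibble (`code_id`, `definition`, ...).
#' @param keywords Named list: `code_id` -> character vector of marker
#'   tokens.
#' @param fp_rate,fn_rate False-positive / false-negative rates in `[0, 1]`.
#' @param seed Integer seed for the noise process.
#' @return A `"classifier_adapter"` with a batch fast path.
#' @export
keyword_classifier <- function(codebook, keywords, fp_rate = 0, fn_rate = 0,
                               seed = 1L) {
  stopifnot(fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1)
  def_to_code <- stats::setNames(codebook$code_id, codebook$definition)

  verdict_for <- function(texts, code_id) {
    kw <- keywords[[code_id]]
    hit <- rep(FALSE, length(texts))
    for (k in kw) hit <- hit | grepl(k, texts, fixed = TRUE)
    if (fp_rate > 0 || fn_rate > 0) {
      u <- keyed_runif(texts, salt = string_hash31(code_id, seed))
      flip <- ifelse(hit, u < fn_rate, u < fp_rate)
      hit <- xor(hit, flip)
    }
    hit
  }

  classifier_adapter(
    name = sprintf("keyword-mock(fp=%.3g, fn=%.3g)", fp_rate, fn_rate),
    classify = function(messages) {
      last_user <- messages$content[max(which(messages$role == "user"))]
      code_id <- def_to_code[[extract_definition(last_user)]]
      text <- extract_target_text(last_user)
      if (verdict_for(text, code_id)) "True." else "False."
    },
    classify_batch = function(texts, code) {
      ifelse(verdict_for(texts, code$code_id), "True.", "False.")
    },
    deterministic = TRUE
  )
}

#' Oracle adapter from an arbitrary truth function
#'
#' Wraps a function `(text, code_id) -> logical` as a classifier adapter.
#' Useful for planted-truth oracles in tests and calibration runs.
#'
#' @param truth Vectorized function of `(texts, code_id)`.
#' @param name Adapter name.
#' @return A `"classifier_adapter"` with a batch fast path.
#' @export
oracle_adapter <- function(truth, name = "oracle") {
  classifier_adapter(
    name = name,
    classify = function(messages) {
      last_user <- messages$content[max(which(messages$role == "user"))]
      text <- extract_target_text(last_user)
      if (isTRUE(truth(text, NA_character_))) "True." else "False."
    },
    classify_batch = function(texts, code) {
      ifelse(truth(texts, code$code_id), "True.", "False.")
    },
    deterministic = TRUE
  )
}

#' Create a summarizer
#'
#' A summarizer turns one prompt batch (the code's definition plus the texts
#' of the segments in the batch) into a summary string.
#'
#' @param name Summarizer name.
#' @param summarize Function `(definition, segment_texts) -> character(1)`.
#' @param deterministic Logical flag.
#' @return An object of class `"codewindow_summarizer"`.
#' @export
summarizer <- function(name, summarize, deterministic = TRUE) {
  structure(list(name = name, summarize = summarize,
                 deterministic = isTRUE(deterministic)),
            class = "codewindow_summarizer")
}

#' Echo summarizer: returns the batch text unchanged
#'
#' @return A `"codewindow_summarizer"`.
#' @export
echo_summarizer <- function() {
  summarizer("echo", function(definition, segment_texts) {
    paste(segment_texts, collapse = " ")
  })
}

#' Extractive mock summarizer: first sentence of each segment
#'
#' @return A `"codewindow_summarizer"`.
#' @export
first_sentence_summarizer <- function() {
  summarizer("first-sentence", function(definition, segment_texts) {
    firsts <- vapply(segment_texts,
                     function(t) split_sentences(t)$text[1],
                     character(1), USE.NAMES = FALSE)
    paste(firsts, collapse = " ")
  })
}
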