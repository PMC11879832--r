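#' Count whitespace-delimited words
#'
#' A word is a maximal run of non-whitespace characters; punctuation stays
#' attached to its word. This single definition is used everywhere word
#' counts appear (sentences, windows, segments, batching budgets).
#'
#' @param x Character vector.
#' @return Integer vector of word counts (0 for empty or all-whitespace
#'   strings).
#' @examples
#' count_words(c("Hij fietste weg.", "  two  words  "))
#' @export
count_words <- function(x) {
  x <- stringr::str_trim(x)
  n <- stringr::str_count(x, "\\S+")
  n[is.na(x)] <- NA_integer_
  as.integer(n)
}

#' Round half away from zero
#'
#' Report-parity rounding: 0.005 rounds to 0.01, unlike [base::round()]'s
#' round-half-even. Used wherever values are rounded to a printed precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an epsilon scaled to x to defeat binary representation of .5
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Deterministic 31-bit hash of a string, cheap enough for bulk use.
# Only the first 200 characters contribute (plus total length), which is
# sufficient to separate any two realistic utterances.
string_hash31 <- function(x, salt = 0L) {
  vapply(x, function(s) {
    if (is.na(s)) s <- ""
    cp <- utf8ToInt(substr(s, 1L, 200L))
    h <- (as.numeric(salt) + nchar(s)) %% 2147483647
    for (v in cp) h <- (h * 131 + v) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Uniform draw in (0,1) keyed deterministically by (string, salt): the draw
# does not depend on call order or the global RNG state, and leaves the
# global RNG untouched.
keyed_runif <- function(x, salt = 0L) {
  hashes <- string_hash31(x, salt)
  vapply(hashes, function(h) {
    withr::with_seed(h, stats::runif(1))
  }, numeric(1))
}

abort_codewindow <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "codewindow_error"), ...)
}

`%||%` <- rlang::`%||%`
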