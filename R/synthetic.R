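#' Specification for a synthetic interview corpus
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' a corpus of interview transcripts (default 38, the scale of the
#' psychosocial-autopsy corpus this workflow was validated on), a codebook
#' of deductive codes (default 33) with heterogeneous prevalence spanning
#' sparse to frequent, planted coded fragments whose lengths follow a
#' right-skewed distribution (shifted gamma, support >= `fragment_min`) with
#' mean 207.62 and SD 190.57 words, and transcripts of roughly 4,000-30,000
#' words. Text is language-neutral token soup with
#' sentence punctuation: each code owns a marker keyword that occurs in
#' every sentence of its planted fragments and nowhere else, which makes the
#' keyword mock classifier an exact ground-truth oracle.
#'
#' `code_prevalence` is the expected number of fragments per code in a
#' transcript of mean length; counts scale linearly with transcript length.
#' The default is a geometric profile from 0.1 to 6 fragments, giving a
#' coded-text density of roughly 55-60% of transcript words.
#'
#' @param n_cases Number of transcripts.
#' @param n_codes Number of codes.
#' @param transcript_words Length-2 numeric: min and max target transcript
#'   words (drawn uniformly).
#' @param fragment_mean,fragment_sd,fragment_min Moments and lower support
#'   bound of the planted fragment-length distribution, in words.
#' @param code_prevalence Numeric vector of length `n_codes`: expected
#'   fragments per mean-length transcript. `NULL` for the default profile.
#' @param multi_code_rate Probability that a planted fragment carries a
#'   second, overlapping code (both codes' keywords in every sentence).
#' @param fp_rate,fn_rate Default classifier noise rates carried on the spec
#'   (used by [make_noisy_oracle()] when rates are not given explicitly).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_cases = 38,
                           n_codes = 33,
                           transcript_words = c(4000, 30000),
                           fragment_mean = 207.62,
                           fragment_sd = 190.57,
                           fragment_min = 10,
                           code_prevalence = NULL,
                           multi_code_rate = 0.1,
                           fp_rate = 0,
                           fn_rate = 0,
                           seed = 1L) {
  if (is.null(code_prevalence)) {
    code_prevalence <- exp(seq(log(0.1), log(6), length.out = n_codes))
  }
  spec <- list(
    n_cases = as.integer(n_cases),
    n_codes = as.integer(n_codes),
    transcript_words = as.numeric(transcript_words),
    fragment_mean = fragment_mean,
    fragment_sd = fragment_sd,
    fragment_min = fragment_min,
    code_prevalence = code_prevalence,
    multi_code_rate = multi_code_rate,
    fp_rate = fp_rate,
    fn_rate = fn_rate,
    seed = as.integer(seed)
  )
  stopifnot(spec$n_cases >= 1, spec$n_codes >= 1,
            length(spec$transcript_words) == 2,
            spec$transcript_words[1] > 0,
            spec$transcript_words[2] >= spec$transcript_words[1],
            spec$fragment_mean > 0, spec$fragment_sd > 0, spec$fragment_min >= 1,
            length(spec$code_prevalence) == spec$n_codes,
            all(spec$code_prevalence >= 0),
            spec$multi_code_rate >= 0, spec$multi_code_rate <= 1,
            spec$fp_rate >= 0, spec$fp_rate <= 1,
            spec$fn_rate >= 0, spec$fn_rate <= 1)
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec: %d cases, %d codes, %.0f-%.0f words, seed %d>\n",
              x$n_cases, x$n_codes, x$transcript_words[1], x$transcript_words[2],
              x$seed))
  invisible(x)
}

synthetic_keywords <- function(n_codes) {
  stats::setNames(as.list(sprintf("topic%02dmarker", seq_len(n_codes))),
                  sprintf("code_%02d", seq_len(n_codes)))
}

filler_vocabulary <- function() {
  # pronounceable two-syllable soup; disjoint from the keyword tokens
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  grid <- expand.grid(c1 = consonants, v1 = vowels, c2 = consonants, v2 = vowels,
                      stringsAsFactors = FALSE)
  paste0(grid$c1, grid$v1, grid$c2, grid$v2)[seq_len(400)]
}

# Draw fragment lengths from a shifted gamma: support >= min with the stated
# mean and SD as the distribution's exact moments (a normal truncated at
# `min` would inflate the mean by ~25% at these parameters, and empirical
# fragment-length distributions are right-skewed anyway).
draw_fragment_lengths <- function(n, mean, sd, min) {
  stopifnot(mean > min)
  if (n == 0) return(integer(0))
  m <- mean - min
  shape <- (m / sd)^2
  as.integer(round(min + stats::rgamma(n, shape = shape, scale = sd^2 / m)))
}

# Cut `total` words into sentences of ~8-14 words; returns an integer vector
# of sentence lengths summing to total (last sentence absorbs the remainder,
# merged up if degenerate).
sentence_lengths <- function(total) {
  if (total <= 0) return(integer(0))
  lens <- integer(0)
  left <- total
  while (left > 0) {
    l <- min(left, sample(8:14, 1))
    lens <- c(lens, l)
    left <- left - l
  }
  if (length(lens) > 1 && lens[length(lens)] < 4) {
    lens[length(lens) - 1L] <- lens[length(lens) - 1L] + lens[length(lens)]
    lens <- lens[-length(lens)]
  }
  lens
}

# Build sentences of `lens` word counts from `vocab`, planting each token of
# `markers` once per sentence (replacing body words, at random positions).
build_sentences <- function(lens, vocab, markers = character()) {
  words <- sample(vocab, sum(lens), replace = TRUE)
  stops <- cumsum(lens)
  starts <- stops - lens + 1L
  vapply(seq_along(lens), function(i) {
    w <- words[starts[i]:stops[i]]
    if (length(markers) > 0) {
      pos <- sample.int(length(w), min(length(markers), length(w)))
      w[pos] <- markers[seq_along(pos)]
    }
    paste0(paste(w, collapse = " "), ".")
  }, character(1))
}

#' Generate a synthetic coded corpus
#'
#' Builds, deterministically from the spec's seed, a corpus of transcripts
#' assembled as alternating filler stretches and planted coded fragments,
#' the matching gold annotations, and a codebook whose positive examples are
#' drawn from the planted fragments (negative examples from filler). Planted
#' fragments never overlap by construction; a configurable share carries a
#' second, overlapping code. An error suggests lowering the prevalence when
#' the expected coded density exceeds 95% of transcript words.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `"synthetic_corpus"`: list with `corpus` (the
#'   sentence tibble), `gold` (fragment annotations with text), `codebook`,
#'   `keywords` (named list), and `spec`.
#' @export
generate_corpus <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mean_w <- mean(spec$transcript_words)
  density <- sum(spec$code_prevalence) * spec$fragment_mean / mean_w
  if (density > 0.95) {
    abort_codewindow(
      sprintf("Expected coded density %.0f%% leaves no room for non-overlapping placement; lower `code_prevalence`.",
              100 * density),
      "codewindow_prevalence_error"
    )
  }
  keywords <- synthetic_keywords(spec$n_codes)
  code_ids <- names(keywords)
  vocab <- filler_vocabulary()

  withr::with_seed(spec$seed, {
    case_ids <- sprintf("case_%02d", seq_len(spec$n_cases))
    targets <- round(stats::runif(spec$n_cases, spec$transcript_words[1],
                                  spec$transcript_words[2]))

    corpus_list <- list()
    gold_list <- list()
    for (ci in seq_len(spec$n_cases)) {
      w_target <- targets[ci]
      lambda <- spec$code_prevalence * w_target / mean_w
      n_frag_per_code <- stats::rpois(spec$n_codes, lambda)
      frag_codes <- rep(seq_len(spec$n_codes), n_frag_per_code)
      n_frag <- length(frag_codes)
      frag_codes <- frag_codes[sample.int(n_frag)]  # shuffle within transcript
      second_code <- ifelse(
        stats::runif(n_frag) < spec$multi_code_rate & spec$n_codes > 1,
        vapply(frag_codes, function(c1) {
          others <- setdiff(seq_len(spec$n_codes), c1)
          others[sample.int(length(others), 1)]
        }, integer(1)),
        NA_integer_
      )
      frag_lens <- draw_fragment_lengths(n_frag, spec$fragment_mean,
                                         spec$fragment_sd, spec$fragment_min)
      filler_total <- max(0, w_target - sum(frag_lens))
      # distribute filler over the n_frag + 1 gaps
      gap_share <- if (n_frag > 0) {
        as.vector(stats::rmultinom(1, filler_total, rep(1, n_frag + 1L)))
      } else {
        filler_total
      }

      sent_text <- character(0)
      spans <- list()
      for (fi in seq_len(n_frag + 1L)) {
        gap_sents <- build_sentences(sentence_lengths(gap_share[fi]), vocab)
        sent_text <- c(sent_text, gap_sents)
        if (fi <= n_frag) {
          markers <- sprintf("topic%02dmarker",
                             c(frag_codes[fi],
                               if (!is.na(second_code[fi])) second_code[fi]))
          frag_sents <- build_sentences(sentence_lengths(frag_lens[fi]),
                                        vocab, markers)
          first <- length(sent_text)
          sent_text <- c(sent_text, frag_sents)
          last <- length(sent_text) - 1L
          for (code_idx in c(frag_codes[fi],
                             if (!is.na(second_code[fi])) second_code[fi])) {
            spans[[length(spans) + 1L]] <- tibble::tibble(
              case_id = case_ids[ci],
              code_id = code_ids[code_idx],
              first_sentence = first,
              last_sentence = last
            )
          }
        }
      }
      wc <- count_words(sent_text)
      corpus_list[[ci]] <- tibble::tibble(
        case_id = case_ids[ci],
        speaker = NA_character_,
        sentence_index = seq_along(sent_text) - 1L,
        text = sent_text,
        word_count = wc,
        start_offset = c(0L, cumsum(wc)[-length(wc)])
      )
      gold_list[[ci]] <- dplyr::bind_rows(spans)
    }
    corpus <- dplyr::bind_rows(corpus_list)
    gold <- dplyr::bind_rows(gold_list)
    gold <- gold_with_text(gold, corpus)

    # codebook: positive example from a planted fragment (or a fresh
    # standalone fragment for unplanted codes), negative example from filler
    codebook <- purrr::map(seq_len(spec$n_codes), function(i) {
      code_id <- code_ids[i]
      kw <- keywords[[code_id]]
      cand <- gold$text[gold$code_id == code_id]
      pos <- if (length(cand) > 0) {
        cand[sample.int(length(cand), 1)]
      } else {
        paste(build_sentences(
          sentence_lengths(draw_fragment_lengths(1, spec$fragment_mean,
                                                 spec$fragment_sd,
                                                 spec$fragment_min)),
          vocab, kw), collapse = " ")
      }
      neg <- paste(build_sentences(sentence_lengths(40), vocab), collapse = " ")
      tibble::tibble(
        code_id = code_id,
        definition = sprintf(
          "Discussion of theme %02d as raised in the interview, marked by the term '%s'",
          i, kw),
        positive_example = pos,
        negative_example = neg
      )
    })
    codebook <- validate_codebook(dplyr::bind_rows(codebook))

    structure(
      list(corpus = corpus, gold = gold, codebook = codebook,
           keywords = keywords, spec = spec),
      class = "synthetic_corpus"
    )
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus: %d cases (%d sentences, %d words), %d codes, %d gold fragments>\n",
              length(unique(x$corpus$case_id)), nrow(x$corpus),
              sum(x$corpus$word_count), nrow(x$codebook), nrow(x$gold)))
  invisible(x)
}

#' Ground-truth oracle classifier with controllable noise
#'
#' Returns a classifier adapter that answers `True` exactly when the queried
#' text overlaps a planted fragment of the queried code — by construction
#' this is equivalent to the code's marker keyword occurring in the text —
#' and then flips the answer independently with probability `fp_rate` (for
#' true negatives) or `fn_rate` (for true positives). Flips are keyed by
#' (text, code, seed), so the verdict stream is reproducible regardless of
#' query order.
#'
#' @param x A `"synthetic_corpus"`.
#' @param fp_rate,fn_rate Noise rates; default to the generating spec's.
#' @param seed Noise seed; defaults to the spec's seed.
#' @return A `"classifier_adapter"`.
#' @export
make_noisy_oracle <- function(x, fp_rate = NULL, fn_rate = NULL, seed = NULL) {
  stopifnot(inherits(x, "synthetic_corpus"))
  keyword_classifier(
    x$codebook, x$keywords,
    fp_rate = fp_rate %||% x$spec$fp_rate,
    fn_rate = fn_rate %||% x$spec$fn_rate,
    seed = seed %||% x$spec$seed
  )
}

#' Write a synthetic corpus in the pipeline's file formats
#'
#' Emits `transcripts.jsonl`, `codebook.csv` and `gold.csv` so the pipeline
#' runs on the files exactly as it would on real data.
#'
#' @param x A `"synthetic_corpus"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_corpus <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_transcripts(x$corpus, file.path(dir, "transcripts.jsonl"))
  readr::write_csv(x$codebook, file.path(dir, "codebook.csv"), progress = FALSE)
  write_gold(x$gold, file.path(dir, "gold.csv"))
  invisible(dir)
}
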