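make_gold_corpus <- function(n_codes = 3, n_cases = 4, seed = 123) {
  generate_corpus(synthetic_spec(
    n_cases = n_cases, n_codes = n_codes,
    transcript_words = c(1500, 3000),
    code_prevalence = rep(2, n_codes),
    multi_code_rate = 0, seed = seed
  ))
}

test_that("level-1 datasets are balanced, seeded and leakage-free", {
  x <- make_gold_corpus()
  items <- build_level1_dataset(x$gold, x$codebook, negatives_per_positive = 1,
                                seed = 42)
  per_code <- dplyr::count(items, code_id, gold)
  for (code in unique(items$code_id)) {
    pc <- per_code[per_code$code_id == code, ]
    expect_equal(pc$n[pc$gold], pc$n[!pc$gold])  # balanced
  }
  # few-shot examples excluded
  for (i in seq_len(nrow(x$codebook))) {
    code <- x$codebook[i, ]
    own <- items[items$code_id == code$code_id, ]
    expect_false(any(own$text %in% c(code$positive_example, code$negative_example)))
  }
  # seed-reproducible
  expect_identical(items,
                   build_level1_dataset(x$gold, x$codebook, 1, seed = 42))
  expect_false(identical(items,
                         build_level1_dataset(x$gold, x$codebook, 1, seed = 43)))
  # ratio 0: positives only
  pos_only <- build_level1_dataset(x$gold, x$codebook, 0, seed = 1)
  expect_true(all(pos_only$gold))
})

test_that("no fragment is both positive and negative for the same code", {
  x <- make_gold_corpus(n_codes = 3)
  items <- build_level1_dataset(x$gold, x$codebook, 1, seed = 9)
  # exhaustive check over every (code, fragment) pair
  clash <- items |>
    dplyr::distinct(code_id, fragment_id, gold) |>
    dplyr::count(code_id, fragment_id) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(clash), 0)
})

test_that("an oversized negative demand errors naming the code", {
  x <- make_gold_corpus(n_codes = 2, n_cases = 2)
  expect_error(build_level1_dataset(x$gold, x$codebook, 1000, seed = 1),
               regexp = "code_0", class = "codewindow_sampling_error")
})

test_that("confusion counts follow the agreement definitions", {
  x <- make_gold_corpus()
  items <- build_level1_dataset(x$gold, x$codebook, 1, seed = 5)

  perfect <- make_noisy_oracle(x)          # noiseless keyword oracle = gold
  counts <- classify_level1(items, x$codebook, perfect)
  expect_equal(sum(counts$fp), 0)
  expect_equal(sum(counts$fn), 0)
  expect_equal(counts$tp + counts$tn + counts$fp + counts$fn,
               as.integer(table(items$code_id)[counts$code_id]))

  always_true <- classifier_adapter("always-true",
                                    classify = function(messages) "True.")
  counts_t <- classify_level1(items, x$codebook, always_true)
  expect_equal(counts_t$fn, rep(0L, nrow(counts_t)))
  expect_equal(counts_t$tn, rep(0L, nrow(counts_t)))
  expect_equal(counts_t$tp, counts$tp + counts$fn)
})

test_that("seeded symmetric noise lands near its nominal rate", {
  x <- generate_corpus(synthetic_spec(
    n_cases = 8, n_codes = 4, transcript_words = c(8000, 12000),
    code_prevalence = rep(8, 4), multi_code_rate = 0, seed = 31
  ))
  items <- build_level1_dataset(x$gold, x$codebook, 1, seed = 8)
  expect_gte(nrow(items), 400)
  noisy <- make_noisy_oracle(x, fp_rate = 0.1, fn_rate = 0.1, seed = 2)
  counts <- classify_level1(items, x$codebook, noisy)
  n <- sum(counts$tp + counts$tn + counts$fp + counts$fn)
  err <- sum(counts$fp + counts$fn) / n
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(err - 0.1), 3 * se)
})

test_that("adapter failures are retried once then default to False", {
  cb <- tiny_codebook(1)
  items <- tibble::tibble(code_id = "code_01", case_id = "c1",
                          fragment_id = "c1:0:0",
                          text = "They spoke about kw01 again.", gold = TRUE)
  calls <- 0L
  flaky <- classifier_adapter("flaky", classify = function(messages) {
    calls <<- calls + 1L
    if (calls == 1L) stop("transient") else "True."
  })
  counts <- classify_level1(items, cb, flaky)
  expect_equal(counts$tp, 1L)   # retry succeeded

  calls2 <- 0L
  broken <- classifier_adapter("broken", classify = function(messages) {
    calls2 <<- calls2 + 1L
    stop("down")
  })
  expect_warning(counts2 <- classify_level1(items, cb, broken),
                 class = "codewindow_adapter_failure")
  expect_equal(counts2$fn, 1L)  # default-False under persistent failure
  expect_equal(calls2, 2L)
})

test_that("window classification covers the windows-by-codes grid", {
  corpus <- uniform_corpus(60, 50)
  cb <- tiny_codebook(3)
  kw <- tiny_keywords(3)
  ad <- keyword_classifier(cb, kw)
  cfg <- pipeline_config()
  w <- make_windows(corpus, cfg)
  v <- classify_windows(corpus, cb, ad, cfg, windows = w)
  expect_equal(nrow(v), nrow(w) * 3)
  expect_equal(dplyr::n_distinct(v$code_id), 3)

  empty <- classify_windows(corpus, cb[0, ], ad, cfg, windows = w)
  expect_equal(nrow(empty), 0)
})

test_that("oracle verdicts fire exactly on windows overlapping planted spans", {
  x <- make_gold_corpus(n_codes = 2, seed = 77)
  cfg <- pipeline_config()
  w <- make_windows(x$corpus, cfg)
  v <- classify_windows(x$corpus, x$codebook, make_noisy_oracle(x), cfg,
                        windows = w)
  joined <- dplyr::inner_join(v, w, by = c("case_id", "window_id"))
  overlap <- purrr::pmap_lgl(
    joined[c("case_id", "code_id", "first_sentence", "last_sentence")],
    function(case_id, code_id, first_sentence, last_sentence) {
      g <- x$gold[x$gold$case_id == case_id & x$gold$code_id == code_id, ]
      any(g$first_sentence <= last_sentence & first_sentence <= g$last_sentence)
    }
  )
  expect_equal(joined$positive, overlap)
})

test_that("batch and scalar adapter paths agree", {
  corpus <- uniform_corpus(20, 40)
  corpus$text[5] <- paste("kw01", corpus$text[5])
  corpus$text[12] <- paste("kw02", corpus$text[12])
  cb <- tiny_codebook(2)
  kw <- tiny_keywords(2)
  batched <- keyword_classifier(cb, kw, fp_rate = 0.2, fn_rate = 0.1, seed = 4)
  scalar <- batched
  scalar$classify_batch <- NULL
  cfg <- pipeline_config()
  vb <- classify_windows(corpus, cb, batched, cfg)
  vs <- classify_windows(corpus, cb, scalar, cfg)
  expect_identical(vb, vs)
})

test_that("the verdict cache makes reruns hit zero classifier calls", {
  corpus <- uniform_corpus(30, 50)
  cb <- tiny_codebook(2)
  calls <- 0L
  counting <- classifier_adapter(
    "counting",
    classify = function(messages) { calls <<- calls + 1L; "False." }
  )
  cache <- withr::local_tempfile(fileext = ".jsonl")
  cfg <- pipeline_config()
  v1 <- classify_windows(corpus, cb, counting, cfg, cache_path = cache)
  first_calls <- calls
  expect_gt(first_calls, 0)
  v2 <- classify_windows(corpus, cb, counting, cfg, cache_path = cache)
  expect_equal(calls, first_calls)   # zero new calls
  expect_identical(v1, v2)
})
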