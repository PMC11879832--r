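#' Run the full coding pipeline on a corpus
#'
#' The end-to-end scan: sliding windows over every transcript, few-shot
#' classification of every (window, code) pair, peak detection with
#' threshold escalation into coded segments, optional per-code summarization
#' and assembly of the case-by-code summary matrix.
#'
#' @param corpus Corpus tibble.
#' @param codebook Codebook tibble.
#' @param adapter A [classifier_adapter()].
#' @param config A [pipeline_config()].
#' @param summarizer Optional [summarizer()]; when supplied, Level-3 outputs
#'   (`summaries`, `matrix`) are produced.
#' @param cache_path Optional verdict cache path (see [classify_windows()]).
#' @param keep_scores Keep per-sentence score tables?
#' @return An object of class `"coding_run"`: list with `windows`,
#'   `verdicts`, `segments`, `thresholds`, `scores`, `summaries`, `matrix`,
#'   `config`.
#' @export
run_pipeline <- function(corpus, codebook, adapter,
                         config = pipeline_config(),
                         summarizer = NULL,
                         cache_path = NULL,
                         keep_scores = FALSE) {
  config <- as_pipeline_config(config)
  windows <- make_windows(corpus, config)
  verdicts <- classify_windows(corpus, codebook, adapter, config,
                               windows = windows, cache_path = cache_path)
  det <- detect_segments(corpus, windows, verdicts, config,
                         keep_scores = keep_scores)
  summaries <- NULL
  matrix <- NULL
  if (!is.null(summarizer)) {
    summaries <- summarize_segments(det$segments, corpus, codebook, summarizer,
                                    budget_words = config$summary_budget_words)
    matrix <- build_matrix(summaries, unique(corpus$case_id), codebook$code_id)
  }
  structure(
    list(windows = windows, verdicts = verdicts, segments = det$segments,
         thresholds = det$thresholds, scores = det$scores,
         summaries = summaries, matrix = matrix, config = config),
    class = "coding_run"
  )
}

#' @export
print.coding_run <- function(x, ...) {
  cat(sprintf("<coding_run: %d windows, %d verdicts (%d positive), %d segments%s>\n",
              nrow(x$windows), nrow(x$verdicts), sum(x$verdicts$positive),
              nrow(x$segments),
              if (!is.null(x$matrix)) {
                sprintf(", %d summary cells", nrow(x$matrix$records))
              } else ""))
  invisible(x)
}

#' Write a run manifest
#'
#' Every output directory carries exactly one manifest recording the
#' configuration snapshot, the seed, the package version, input file digests
#' and per-stage record counts — enough to reproduce the run.
#'
#' @param dir Output directory.
#' @param config A [pipeline_config()].
#' @param inputs Named character vector of input file paths (digested).
#' @param counts Named list/vector of per-stage record counts.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, inputs = character(), counts = list()) {
  digests <- vapply(inputs, function(p) {
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  }, character(1))
  manifest <- list(
    tool = "codewindow",
    version = as.character(utils::packageVersion("codewindow")),
    config = unclass(config),
    seed = config$seed,
    inputs = as.list(digests),
    counts = counts
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Simulate a synthetic corpus to disk
#'
#' Generates a [synthetic_spec()] corpus and writes transcripts, codebook,
#' gold annotations and a manifest to `out_dir`.
#'
#' @param spec A [synthetic_spec()] (or a list of its arguments).
#' @param out_dir Output directory.
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(spec = synthetic_spec(), out_dir) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  x <- generate_corpus(spec)
  write_synthetic_corpus(x, out_dir)
  write_manifest(
    out_dir,
    pipeline_config(seed = spec$seed),
    inputs = c(transcripts = file.path(out_dir, "transcripts.jsonl"),
               codebook = file.path(out_dir, "codebook.csv"),
               gold = file.path(out_dir, "gold.csv")),
    counts = list(cases = spec$n_cases, codes = spec$n_codes,
                  sentences = nrow(x$corpus), gold_fragments = nrow(x$gold))
  )
  invisible(out_dir)
}

#' Run the coding pipeline from files
#'
#' Reads transcripts and codebook, runs [run_pipeline()] and writes verdicts
#' (cached), segments, summaries, the summary matrix and a manifest.
#'
#' @param transcripts_path,codebook_path Input files.
#' @param adapter A [classifier_adapter()].
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param summarizer A [summarizer()]; default [echo_summarizer()].
#' @return The `"coding_run"`, invisibly.
#' @export
run_code <- function(transcripts_path, codebook_path, adapter, out_dir,
                     config = pipeline_config(),
                     summarizer = echo_summarizer()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- read_transcripts(transcripts_path)
  codebook <- read_codebook(codebook_path)
  run <- run_pipeline(corpus, codebook, adapter, config,
                      summarizer = summarizer,
                      cache_path = file.path(out_dir, "verdicts.jsonl"))
  if (nrow(run$segments) > 0) {
    write_segments(run$segments, file.path(out_dir, "segments.jsonl"))
  }
  if (!is.null(run$matrix)) {
    write_matrix(run$matrix, file.path(out_dir, "matrix.csv"))
  }
  write_manifest(
    out_dir, config,
    inputs = c(transcripts = transcripts_path, codebook = codebook_path),
    counts = list(windows = nrow(run$windows), verdicts = nrow(run$verdicts),
                  segments = nrow(run$segments),
                  summaries = if (!is.null(run$summaries)) nrow(run$summaries) else 0)
  )
  invisible(run)
}

#' Evaluate pipeline outputs against gold annotations
#'
#' Produces the full three-level report set: per-code binary confusion
#' metrics with kappa (from a Level-1 run or supplied counts), segment
#' frequency factors, occurrence accuracy, and (when ratings are given)
#' rating tallies. Reports are written as CSV in the layouts of the
#' benchmark tables plus one machine-readable JSON with full-precision
#' values.
#'
#' @param binary_counts Per-code confusion tibble (`code_id`, `tp`, `tn`,
#'   `fp`, `fn`), or `NULL` to skip.
#' @param segments Detected segment tibble, or `NULL`.
#' @param gold Gold fragment tibble, or `NULL`.
#' @param cases,codes Universe vectors (required with `segments`/`gold`).
#' @param ratings Ratings tibble, or `NULL`.
#' @param out_dir Output directory.
#' @return A list of the computed report objects, invisibly.
#' @export
run_evaluate <- function(out_dir,
                         binary_counts = NULL,
                         segments = NULL, gold = NULL,
                         cases = NULL, codes = NULL,
                         ratings = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  if (!is.null(binary_counts)) {
    ev <- evaluate_binary(binary_counts)
    out$binary <- ev
    readr::write_csv(report_binary(ev), file.path(out_dir, "report_binary.csv"),
                     progress = FALSE)
  }
  if (!is.null(segments) && !is.null(gold)) {
    cases <- cases %||% sort(unique(c(segments$case_id, gold$case_id)))
    codes <- codes %||% sort(unique(c(segments$code_id, gold$code_id)))
    miss_cases <- setdiff(unique(c(segments$case_id, gold$case_id)), cases)
    miss_codes <- setdiff(unique(c(segments$code_id, gold$code_id)), codes)
    if (length(miss_cases) > 0 || length(miss_codes) > 0) {
      abort_codewindow(
        paste0("Ids outside the declared universe: ",
               paste(c(miss_cases, miss_codes), collapse = ", ")),
        "codewindow_universe_error"
      )
    }
    freq <- dplyr::full_join(
      segments |> dplyr::count(.data$code_id, name = "llm_count"),
      gold |> dplyr::count(.data$code_id, name = "researcher_count"),
      by = "code_id"
    ) |>
      tidyr::replace_na(list(llm_count = 0L, researcher_count = 0L))
    out$frequency <- frequency_factors(freq)
    readr::write_csv(report_frequencies(out$frequency),
                     file.path(out_dir, "report_frequencies.csv"),
                     progress = FALSE)
    out$occurrence <- occurrence_accuracy(
      occurrence_matrix(segments, cases, codes),
      occurrence_matrix(gold, cases, codes)
    )
    readr::write_csv(report_occurrence(out$occurrence),
                     file.path(out_dir, "report_occurrence.csv"),
                     progress = FALSE)
  }
  if (!is.null(ratings)) {
    out$ratings <- rating_tally(ratings)
    readr::write_csv(out$ratings$per_rater,
                     file.path(out_dir, "report_ratings.csv"),
                     progress = FALSE)
  }
  json <- list(
    binary = if (!is.null(out$binary)) {
      list(per_code = tidy(out$binary), aggregate = glance(out$binary))
    },
    frequency = if (!is.null(out$frequency)) {
      list(per_code = out$frequency$per_code, summary = out$frequency$summary)
    },
    occurrence = if (!is.null(out$occurrence)) out$occurrence,
    ratings = if (!is.null(out$ratings)) out$ratings$per_rater
  )
  jsonlite::write_json(json[!vapply(json, is.null, logical(1))],
                       file.path(out_dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Benchmark-layout binary report
#'
#' Per-code rows in the benchmark column layout (`Count`, counts, printed
#' `Sens.`/`Spec.` mapped to the predictive-agreement pair, `ACC`, `CK`,
#' all rounded half-up to 2 decimals) plus a Total/mean row combining pooled
#' counts with unweighted mean ACC/CK — the aggregation the benchmark table
#' prints.
#'
#' @param ev A `"coding_eval"` from [evaluate_binary()].
#' @return A tibble.
#' @export
report_binary <- function(ev) {
  m <- ev$metrics
  a <- ev$aggregate
  per <- tibble::tibble(
    code = m$code_id,
    count = m$total,
    tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
    sens = round_half_up(m$positive_predictive_agreement, 2),
    spec = round_half_up(m$negative_predictive_agreement, 2),
    acc = round_half_up(m$accuracy, 2),
    ck = round_half_up(m$kappa, 2)
  )
  total_row <- tibble::tibble(
    code = "Total/mean",
    count = sum(m$total),
    tp = a$tp, tn = a$tn, fp = a$fp, fn = a$fn,
    sens = round_half_up(a$tp / (a$tp + a$fp), 2),
    spec = round_half_up(a$tn / (a$tn + a$fn), 2),
    acc = round_half_up(a$mean_accuracy, 2),
    ck = round_half_up(a$mean_kappa, 2)
  )
  dplyr::bind_rows(per, total_row)
}

#' Benchmark-layout frequency report
#'
#' @param fr The list returned by [frequency_factors()].
#' @return A tibble with per-code rows and a Total/mean row.
#' @export
report_frequencies <- function(fr) {
  per <- tibble::tibble(
    code = fr$per_code$code_id,
    llm_count = fr$per_code$llm_count,
    researcher_count = fr$per_code$researcher_count,
    factor = fr$per_code$factor_1dp
  )
  dplyr::bind_rows(per, tibble::tibble(
    code = "Total/mean",
    llm_count = sum(per$llm_count),
    researcher_count = sum(per$researcher_count),
    factor = fr$summary$mean_factor_1dp
  ))
}

#' Benchmark-layout occurrence report
#'
#' @param occ The list returned by [occurrence_accuracy()].
#' @return A tibble with per-code rows and a pooled Total row.
#' @export
report_occurrence <- function(occ) {
  per <- occ$per_code |>
    dplyr::transmute(code = .data$code_id, .data$tp, .data$tn, .data$fp,
                     .data$fn, acc = round_half_up(.data$accuracy, 2))
  dplyr::bind_rows(per, tibble::tibble(
    code = "Total",
    tp = occ$pooled$tp, tn = occ$pooled$tn,
    fp = occ$pooled$fp, fn = occ$pooled$fn,
    acc = round_half_up(occ$pooled$accuracy, 2)
  ))
}
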