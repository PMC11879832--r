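#' Bundled reference benchmark tables
#'
#' The package ships the published benchmark results of this coding workflow
#' — a comparison between an LLM coder and human researchers on 38
#' psychosocial-autopsy interviews with 33 deductive codes — as plain-CSV
#' count tables. They serve as worked fixtures: every derived statistic in
#' them (accuracy, kappa, factors, percentages) can be re-computed from the
#' printed counts with this package's metric functions.
#'
#' * `reference_binary_counts()`: per-code confusion counts of the binary
#'   fragment-classification task, with the printed derived columns
#'   (`sens`, `spec`, `acc`, `ck`). The printed `sens`/`spec` columns
#'   correspond to this package's predictive-agreement pair (see
#'   [code_metrics()]).
#' * `reference_window_frequencies()`: per-code segment counts of the
#'   sliding-window run for the LLM and the researchers, with the printed
#'   1-decimal `factor`.
#' * `reference_window_occurrence()`: per-code confusion counts of
#'   dichotomous code occurrence over the 38 transcripts, with printed
#'   accuracy.
#' * `reference_summary_ratings()`: per-code counts of `good` / `adequate` /
#'   `poor` summary ratings for two independent raters.
#'
#' @return A tibble (layout above).
#' @name reference_tables
NULL

reference_path <- function(file) {
  system.file("extdata", file, package = "codewindow", mustWork = TRUE)
}

#' @rdname reference_tables
#' @export
reference_binary_counts <- function() {
  readr::read_csv(reference_path("reference_binary_counts.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_tables
#' @export
reference_window_frequencies <- function() {
  readr::read_csv(reference_path("reference_window_frequencies.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_tables
#' @export
reference_window_occurrence <- function() {
  readr::read_csv(reference_path("reference_window_occurrence.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_tables
#' @export
reference_summary_ratings <- function() {
  readr::read_csv(reference_path("reference_summary_ratings.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Write the bundled reference tables as CSV files
#'
#' Convenience for downstream tooling that wants the fixtures on disk next
#' to pipeline outputs.
#'
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_reference_tables <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in c("reference_binary_counts.csv", "reference_window_frequencies.csv",
              "reference_window_occurrence.csv", "reference_summary_ratings.csv")) {
    file.copy(reference_path(f), file.path(dir, f), overwrite = TRUE)
  }
  invisible(dir)
}
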