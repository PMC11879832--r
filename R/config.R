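#' Pipeline configuration
#'
#' Collects every numeric parameter of the sliding-window coding pipeline in
#' one validated object. The defaults are the published operating point of
#' the methodology: windows of at most 300 words, a stride of at least 75
#' words between window starts, a detection threshold at 51% of the maximum
#' window overlap (rounded up), and a 3,000-word cap on detected segments
#' (the precondition for single-prompt summarization).
#'
#' @param window_max_words Maximum words per sliding window. Default 300.
#' @param min_stride_words Minimum words between the start offsets of
#'   consecutive windows. Default 75.
#' @param threshold_fraction Fraction of the maximum window overlap at which
#'   the initial detection threshold is set (rounded up to a whole count).
#'   Default 0.51.
#' @param segment_word_cap Maximum words allowed in a detected segment before
#'   the threshold is escalated. Default 3000.
#' @param smoothing_radius Radius (in sentences) of the moving average applied
#'   to per-sentence positive-window counts; the averaging window is
#'   `2 * smoothing_radius + 1` sentences, shrinking at transcript edges.
#'   The source methodology does not state a width; 2 is this package's
#'   default and the value is always configurable. Use 0 to disable.
#' @param summary_budget_words Word budget of a single summarization prompt.
#'   Defaults to `segment_word_cap`.
#' @param seed Integer seed used by seeded operations that take this config.
#'
#' @return A list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config()
#' max_window_overlap(cfg)   # 4
#' initial_threshold(cfg)    # 3
#' @export
pipeline_config <- function(window_max_words = 300,
                            min_stride_words = 75,
                            threshold_fraction = 0.51,
                            segment_word_cap = 3000,
                            smoothing_radius = 2,
                            summary_budget_words = segment_word_cap,
                            seed = 1L) {
  cfg <- list(
    window_max_words = as.integer(window_max_words),
    min_stride_words = as.integer(min_stride_words),
    threshold_fraction = as.numeric(threshold_fraction),
    segment_word_cap = as.integer(segment_word_cap),
    smoothing_radius = as.integer(smoothing_radius),
    summary_budget_words = as.integer(summary_budget_words),
    seed = as.integer(seed)
  )
  if (!(cfg$window_max_words >= cfg$min_stride_words && cfg$min_stride_words > 0)) {
    abort_codewindow(
      "`window_max_words` must be at least `min_stride_words`, which must be positive.",
      "codewindow_config_error"
    )
  }
  if (!(cfg$threshold_fraction > 0 && cfg$threshold_fraction <= 1)) {
    abort_codewindow(
      "`threshold_fraction` must lie in (0, 1].",
      "codewindow_config_error"
    )
  }
  if (cfg$segment_word_cap < cfg$window_max_words) {
    abort_codewindow(
      "`segment_word_cap` must be at least `window_max_words`.",
      "codewindow_config_error"
    )
  }
  if (cfg$smoothing_radius < 0) {
    abort_codewindow("`smoothing_radius` must be >= 0.", "codewindow_config_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  window:    <= %d words, stride >= %d words (max overlap %d)\n",
              x$window_max_words, x$min_stride_words, max_window_overlap(x)))
  cat(sprintf("  threshold: ceil(%.2f * %d) = %d, segment cap %d words\n",
              x$threshold_fraction, max_window_overlap(x),
              initial_threshold(x), x$segment_word_cap))
  cat(sprintf("  smoothing: radius %d; summary budget %d words; seed %d\n",
              x$smoothing_radius, x$summary_budget_words, x$seed))
  invisible(x)
}

as_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.list(config)) return(do.call(pipeline_config, config))
  abort_codewindow("`config` must be a pipeline_config or a list of parameters.",
                   "codewindow_config_error")
}
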