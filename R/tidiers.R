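#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Evaluate a binary coding run
#'
#' Bundles per-code confusion counts with the full metric family and both
#' aggregations (unweighted code means and pooled counts) into one object
#' with broom-style accessors: [tidy()] returns the per-code metric table,
#' [glance()] the one-row aggregate, and `autoplot()` a kappa-by-code chart.
#'
#' @param counts Per-code confusion tibble (`code_id`, `tp`, `tn`, `fp`,
#'   `fn`), e.g. from [classify_level1()] or a reference table.
#' @return An object of class `"coding_eval"`.
#' @examples
#' ev <- evaluate_binary(tibble::tibble(code_id = c("a", "b"),
#'                                      tp = c(12, 47), tn = c(12, 47),
#'                                      fp = c(0, 2), fn = c(0, 2)))
#' tidy(ev)
#' glance(ev)
#' @export
evaluate_binary <- function(counts) {
  metrics <- code_metrics(counts)
  structure(
    list(metrics = metrics, aggregate = aggregate_codes(metrics)),
    class = "coding_eval"
  )
}

#' @export
print.coding_eval <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<coding_eval: %d codes; mean accuracy %.2f (SD %.2f), mean kappa %.2f [%s]>\n",
              a$n_codes, a$mean_accuracy, a$sd_accuracy, a$mean_kappa,
              interpret_kappa(a$mean_kappa)))
  invisible(x)
}

#' @rdname evaluate_binary
#' @param x A `"coding_eval"` object.
#' @param ... Unused.
#' @method tidy coding_eval
#' @export
tidy.coding_eval <- function(x, ...) {
  x$metrics
}

#' @rdname evaluate_binary
#' @method glance coding_eval
#' @export
glance.coding_eval <- function(x, ...) {
  x$aggregate
}

#' Plot per-code kappa with Landis-Koch bands
#'
#' @param object A `"coding_eval"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coding_eval
#' @export
autoplot.coding_eval <- function(object, ...) {
  df <- object$metrics |>
    dplyr::mutate(code_id = stats::reorder(.data$code_id, .data$kappa))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kappa, y = .data$code_id,
                                   fill = .data$kappa_band)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(0.2, 0.4, 0.6, 0.8),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "Cohen's kappa", y = NULL, fill = "agreement") +
    ggplot2::theme_minimal()
}

#' Plot the peak-detection profile of one case and code
#'
#' Shows raw positive-window counts, the smoothed curve, the detection
#' threshold and the detected segments — the working view of the
#' peak-detection step.
#'
#' @param scores Score tibble (`sentence_index`, `raw_count`, `smoothed`)
#'   for one (case, code), e.g. from [detect_with_escalation()].
#' @param segments Matching segment tibble (may have zero rows).
#' @param threshold The threshold used.
#' @return A ggplot.
#' @export
plot_detection_profile <- function(scores, segments, threshold) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$sentence_index)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$raw_count),
                      fill = "grey80", width = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "#d95f02") +
    ggplot2::labs(x = "sentence index", y = "positive-window count") +
    ggplot2::theme_minimal()
  if (nrow(segments) > 0) {
    p <- p + ggplot2::annotate(
      "rect",
      xmin = segments$first_sentence - 0.5, xmax = segments$last_sentence + 0.5,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "#1b9e77"
    )
  }
  p
}
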