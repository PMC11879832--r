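#' Confusion metrics and Cohen's kappa per code
#'
#' Computes, for each row of confusion counts, the full family of agreement
#' statistics. Two naming caveats matter when comparing with published
#' deductive-coding benchmarks:
#'
#' * `positive_predictive_agreement` is `tp / (tp + fp)` (PPV) and
#'   `negative_predictive_agreement` is `tn / (tn + fn)` (NPV). Benchmark
#'   tables for this workflow print these two under the headings "Sens." and
#'   "Spec."; the conventional rates `true_positive_rate` (`tp / (tp + fn)`)
#'   and `true_negative_rate` (`tn / (tn + fp)`) are also computed, under
#'   unambiguous names.
#' * Cohen's kappa uses `(p_o - p_e) / (1 - p_e)` with `p_o` the accuracy and
#'   `p_e` the product-marginal chance agreement
#'   `((tp+fn)(tp+fp) + (tn+fp)(tn+fn)) / total^2`; perfect agreement with
#'   `p_e = 1` is reported as kappa 1.
#'
#' A zero denominator makes the affected rate `NA` (undefined, distinct from
#' 0) and triggers a warning.
#'
#' @param counts Tibble with integer columns `tp`, `tn`, `fp`, `fn` (other
#'   columns, e.g. `code_id`, are carried through). Every row must have a
#'   positive total.
#' @return `counts` with added columns `total`, `accuracy`,
#'   `positive_predictive_agreement`, `negative_predictive_agreement`,
#'   `true_positive_rate`, `true_negative_rate`, `kappa`, `kappa_band`.
#' @examples
#' code_metrics(tibble::tibble(tp = 47, tn = 47, fp = 2, fn = 2))
#' @export
code_metrics <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (any(total <= 0)) {
    abort_codewindow("Confusion counts must have a positive total.",
                     "codewindow_metric_error")
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  po <- (counts$tp + counts$tn) / total
  pe <- ((counts$tp + counts$fn) * (counts$tp + counts$fp) +
           (counts$tn + counts$fp) * (counts$tn + counts$fn)) / total^2
  kappa <- ifelse(pe == 1, ifelse(po == 1, 1, NA_real_), (po - pe) / (1 - pe))
  out <- counts |>
    dplyr::mutate(
      total = total,
      accuracy = po,
      positive_predictive_agreement = safe_div(counts$tp, counts$tp + counts$fp),
      negative_predictive_agreement = safe_div(counts$tn, counts$tn + counts$fn),
      true_positive_rate = safe_div(counts$tp, counts$tp + counts$fn),
      true_negative_rate = safe_div(counts$tn, counts$tn + counts$fp),
      kappa = kappa,
      kappa_band = interpret_kappa(kappa)
    )
  n_undef <- sum(is.na(out$positive_predictive_agreement) |
                   is.na(out$negative_predictive_agreement) |
                   is.na(out$true_positive_rate) |
                   is.na(out$true_negative_rate) |
                   is.na(out$kappa))
  if (n_undef > 0) {
    rlang::warn(sprintf("%d row(s) have undefined rates (zero denominator); reported as NA.",
                        n_undef),
                class = "codewindow_undefined_rate")
  }
  out
}

#' Interpret Cohen's kappa with the Landis-Koch bands
#'
#' Values are rounded half-up to 2 decimals before banding: below 0 is "no
#' agreement"; 0-0.20 "slight"; 0.21-0.40 "fair"; 0.41-0.60 "moderate";
#' 0.61-0.80 "substantial"; 0.81-1 "nearly perfect".
#'
#' @param k Numeric vector of kappa values in `[-1, 1]` (NA allowed).
#' @return A character vector of band labels.
#' @examples
#' interpret_kappa(c(0.68, -0.05, 0.205))
#' @export
interpret_kappa <- function(k) {
  k2 <- round_half_up(k, 2)
  dplyr::case_when(
    is.na(k2) ~ NA_character_,
    k2 < 0 ~ "no agreement",
    k2 <= 0.20 ~ "slight",
    k2 <= 0.40 ~ "fair",
    k2 <= 0.60 ~ "moderate",
    k2 <= 0.80 ~ "substantial",
    TRUE ~ "nearly perfect"
  )
}

#' Aggregate per-code metrics: unweighted means and pooled counts
#'
#' Two aggregations with different meanings, both always reported: the
#' unweighted mean treats each code as one observation regardless of its
#' item count; the pooled aggregation sums the confusion counts over codes
#' and recomputes the metrics on the sums. They differ whenever per-code
#' item counts are heterogeneous.
#'
#' @param metrics Per-code metric tibble from [code_metrics()].
#' @return A one-row tibble: `n_codes`, `mean_accuracy`, `sd_accuracy`,
#'   `mean_kappa`, `sd_kappa`, pooled `tp`/`tn`/`fp`/`fn`,
#'   `pooled_accuracy`, `pooled_kappa`.
#' @export
aggregate_codes <- function(metrics) {
  stopifnot(nrow(metrics) >= 1)
  pooled <- code_metrics(tibble::tibble(
    tp = sum(metrics$tp), tn = sum(metrics$tn),
    fp = sum(metrics$fp), fn = sum(metrics$fn)
  ))
  tibble::tibble(
    n_codes = nrow(metrics),
    mean_accuracy = mean(metrics$accuracy),
    sd_accuracy = ifelse(nrow(metrics) > 1, stats::sd(metrics$accuracy), 0),
    mean_kappa = mean(metrics$kappa),
    sd_kappa = ifelse(nrow(metrics) > 1, stats::sd(metrics$kappa), 0),
    tp = pooled$tp, tn = pooled$tn, fp = pooled$fp, fn = pooled$fn,
    pooled_accuracy = pooled$accuracy,
    pooled_kappa = pooled$kappa
  )
}

#' Relative code-frequency factors
#'
#' The factor is the number of segments the classifier pipeline assigned a
#' code divided by the number the researchers assigned it — a measure of the
#' pipeline's tendency to emphasize particular codes, reported because
#' sliding-window segment counts are not expected to match fragment counts
#' in absolute terms. Codes with a zero researcher count have an undefined
#' factor: they are excluded from the mean/median aggregation and listed
#' separately.
#'
#' @param freq Tibble with columns `code_id`, `llm_count`,
#'   `researcher_count`.
#' @return A list: `per_code` (tibble with full-precision `factor` and
#'   `factor_1dp` rounded half-up to one decimal), `summary` (one-row
#'   tibble: `mean_factor`, `median_factor`, plus 1-dp versions),
#'   `undefined` (codes with researcher count 0).
#' @export
frequency_factors <- function(freq) {
  per <- freq |>
    dplyr::mutate(
      factor = ifelse(.data$researcher_count > 0,
                      .data$llm_count / .data$researcher_count, NA_real_),
      factor_1dp = round_half_up(.data$factor, 1)
    )
  defined <- per[!is.na(per$factor), ]
  list(
    per_code = per,
    summary = tibble::tibble(
      n_codes = nrow(defined),
      mean_factor = mean(defined$factor),
      median_factor = stats::median(defined$factor),
      mean_factor_1dp = round_half_up(mean(defined$factor), 1),
      median_factor_1dp = round_half_up(stats::median(defined$factor), 1)
    ),
    undefined = per[is.na(per$factor), ]
  )
}

#' Dichotomous occurrence matrix from detected segments
#'
#' Marks a code as present in a transcript when at least one segment was
#' detected (or, for gold data, at least one fragment annotated).
#'
#' @param x Tibble with `case_id`, `code_id` rows (segments or gold
#'   fragments).
#' @param cases,codes Character vectors spanning the full universe.
#' @return A long occurrence tibble: `case_id`, `code_id`, `present`.
#' @export
occurrence_matrix <- function(x, cases, codes) {
  tidyr::crossing(case_id = cases, code_id = codes) |>
    dplyr::left_join(
      x |> dplyr::distinct(.data$case_id, .data$code_id) |>
        dplyr::mutate(present = TRUE),
      by = c("case_id", "code_id")
    ) |>
    dplyr::mutate(present = !is.na(.data$present))
}

#' Accuracy of binary code occurrence against gold
#'
#' Compares the dichotomous presence of each code in each transcript between
#' the pipeline and the gold annotations. Each (case, code) cell contributes
#' one of TP/TN/FP/FN; per-code confusion counts and the pooled accuracy
#' over all cells are returned.
#'
#' @param model_occ,gold_occ Long occurrence tibbles from
#'   [occurrence_matrix()] sharing the same cases and codes.
#' @return A list: `per_code` (metrics tibble), `pooled` (one-row tibble
#'   with summed counts and `accuracy`).
#' @export
occurrence_accuracy <- function(model_occ, gold_occ) {
  key_m <- paste(model_occ$case_id, model_occ$code_id)
  key_g <- paste(gold_occ$case_id, gold_occ$code_id)
  if (!setequal(key_m, key_g) || length(key_m) != length(key_g)) {
    abort_codewindow("Occurrence matrices do not share the same cases and codes.",
                     "codewindow_shape_error")
  }
  joined <- dplyr::inner_join(
    model_occ |> dplyr::rename(model = "present"),
    gold_occ |> dplyr::rename(gold = "present"),
    by = c("case_id", "code_id")
  )
  per_code <- joined |>
    dplyr::group_by(.data$code_id) |>
    dplyr::summarise(
      tp = sum(.data$gold & .data$model),
      tn = sum(!.data$gold & !.data$model),
      fp = sum(!.data$gold & .data$model),
      fn = sum(.data$gold & !.data$model),
      .groups = "drop"
    ) |>
    dplyr::mutate(accuracy = (.data$tp + .data$tn) /
                    (.data$tp + .data$tn + .data$fp + .data$fn))
  pooled <- tibble::tibble(
    tp = sum(per_code$tp), tn = sum(per_code$tn),
    fp = sum(per_code$fp), fn = sum(per_code$fn)
  ) |>
    dplyr::mutate(accuracy = (.data$tp + .data$tn) /
                    (.data$tp + .data$tn + .data$fp + .data$fn))
  list(per_code = per_code, pooled = pooled)
}

#' Tally summary ratings per rater and per code
#'
#' Counts `good` / `adequate` / `poor` ratings for each rater, with
#' percentages of the rater's total rounded half-up to whole percents, plus
#' a per-code cross-tabulation.
#'
#' @param ratings Ratings tibble (`case_id`, `code_id`, `rater`, `rating`),
#'   validated as in [read_ratings()].
#' @return A list: `per_rater` (tibble: `rater`, `rating`, `n`, `percent`),
#'   `per_code` (wide tibble of counts per code and rater).
#' @export
rating_tally <- function(ratings) {
  ratings <- validate_ratings(ratings)
  levels <- c("good", "adequate", "poor")
  per_rater <- ratings |>
    dplyr::mutate(rating = factor(.data$rating, levels = levels)) |>
    dplyr::count(.data$rater, .data$rating, .drop = FALSE) |>
    dplyr::group_by(.data$rater) |>
    dplyr::mutate(percent = round_half_up(100 * .data$n / sum(.data$n))) |>
    dplyr::ungroup() |>
    dplyr::mutate(rating = as.character(.data$rating))
  per_code <- ratings |>
    dplyr::mutate(rating = factor(.data$rating, levels = levels)) |>
    dplyr::count(.data$code_id, .data$rater, .data$rating, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = c("rater", "rating"), values_from = "n",
                       names_sep = "_", values_fill = 0L)
  list(per_rater = per_rater, per_code = per_code)
}

#' Expand a rating count table into rating records
#'
#' Published rating results are often reported as per-code counts per rater.
#' This helper expands such a table into one record per rated summary (with
#' synthetic sequential case ids per code) so the record-level tooling
#' applies.
#'
#' @param counts Tibble with columns `code`, `rater`, `good`, `adequate`,
#'   `poor`.
#' @return A ratings tibble (`case_id`, `code_id`, `rater`, `rating`).
#' @export
ratings_from_counts <- function(counts) {
  rows <- purrr::pmap(counts, function(code, rater, good, adequate, poor) {
    rating <- rep(c("good", "adequate", "poor"), times = c(good, adequate, poor))
    tibble::tibble(
      case_id = sprintf("case%02d", seq_along(rating)),
      code_id = code,
      rater = as.character(rater),
      rating = rating
    )
  })
  dplyr::bind_rows(rows)
}
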