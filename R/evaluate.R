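#' Score cohort predictions against planted truth
#'
#' A prediction is counted correct only when it is unambiguous and its
#' unordered phenotype pair equals the planted pair; an ambiguous call is an
#' error even if the true pair is among the tied optima, mirroring how an
#' equal-score Rh+/Rh- tie should be scored as a miss rather than a guess.
#'
#' @param truth A tibble with `sample_id`, `row_a`, `row_b` (planted
#'   phenotype labels), e.g. from [simulate_cohort()] or a `truth.tsv`.
#' @param predictions A tibble of [glance()] rows (needs `sample`,
#'   `phenotype_a`, `phenotype_b`, `ambiguous`), e.g. from
#'   [predict_cohort()].
#' @return A `bg_eval` object. [glance()] gives the one-row summary
#'   (overall accuracy, ambiguity rate); [tidy()] the per-phenotype recall
#'   in `correct/total` style; `$samples` the per-sample scoring.
#' @export
evaluate_cohort <- function(truth, predictions) {
  truth <- as_tibble(truth)
  predictions <- as_tibble(predictions)
  need_t <- c("sample_id", "row_a", "row_b")
  need_p <- c("sample", "phenotype_a", "phenotype_b", "ambiguous")
  if (!all(need_t %in% names(truth))) {
    abort("truth needs columns sample_id, row_a, row_b",
          class = "hemotyper_validation_error")
  }
  if (!all(need_p %in% names(predictions))) {
    abort("predictions need columns sample, phenotype_a, phenotype_b, ambiguous",
          class = "hemotyper_validation_error")
  }
  m <- match(truth$sample_id, predictions$sample)
  if (anyNA(m) || nrow(predictions) != nrow(truth)) {
    abort("truth and predictions do not cover the same samples",
          class = "hemotyper_validation_error")
  }
  p <- predictions[m, ]

  true_pair <- paste(pmin(truth$row_a, truth$row_b),
                     pmax(truth$row_a, truth$row_b), sep = " / ")
  pred_pair <- paste(pmin(p$phenotype_a, p$phenotype_b),
                     pmax(p$phenotype_a, p$phenotype_b), sep = " / ")
  correct <- !is.na(pred_pair) & !p$ambiguous & pred_pair == true_pair

  samples <- tibble(
    sample_id = truth$sample_id,
    true_pair = true_pair, predicted_pair = pred_pair,
    ambiguous = p$ambiguous, correct = correct
  )

  per_phen <- tibble(
    phenotype = c(truth$row_a, truth$row_b),
    correct = rep(correct, 2L),
    sample_id = rep(truth$sample_id, 2L)
  ) |>
    distinct(.data$phenotype, .data$sample_id, .keep_all = TRUE) |>
    group_by(.data$phenotype) |>
    summarise(n_true = dplyr::n(), n_correct = sum(.data$correct),
              recall = .data$n_correct / .data$n_true,
              .groups = "drop") |>
    mutate(shown_as = sprintf("%d/%d", .data$n_correct, .data$n_true)) |>
    arrange(.data$phenotype)

  structure(
    list(
      samples = samples,
      per_phenotype = per_phen,
      n = nrow(samples),
      n_correct = sum(correct),
      accuracy = mean(correct),
      ambiguity_rate = mean(p$ambiguous, na.rm = TRUE)
    ),
    class = "bg_eval"
  )
}

#' @export
print.bg_eval <- function(x, ...) {
  cat(sprintf("<bg_eval> %d sample(s): accuracy %.4f (%d/%d), ambiguity rate %.4f\n",
              x$n, x$accuracy, x$n_correct, x$n, x$ambiguity_rate))
  print(x$per_phenotype, ...)
  invisible(x)
}

#' @rdname evaluate_cohort
#' @param x A `bg_eval`.
#' @param ... Unused.
#' @method tidy bg_eval
#' @export
tidy.bg_eval <- function(x, ...) x$per_phenotype

#' @rdname evaluate_cohort
#' @method glance bg_eval
#' @export
glance.bg_eval <- function(x, ...) {
  tibble(n = x$n, n_correct = x$n_correct, accuracy = x$accuracy,
         ambiguity_rate = x$ambiguity_rate)
}

#' Plot per-phenotype recall of a cohort evaluation
#'
#' @param object A `bg_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bg_eval
#' @export
autoplot.bg_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phenotype, y = .data$recall)) +
    ggplot2::geom_col(fill = "#0072B2") +
    ggplot2::geom_text(ggplot2::aes(label = .data$shown_as), vjust = -0.4,
                       size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = NULL, y = "recall",
                  title = sprintf("overall accuracy %.3f (n = %d)",
                                  object$accuracy, object$n)) +
    ggplot2::theme_minimal()
}
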