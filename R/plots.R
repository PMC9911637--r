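#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cross-validation curve
#'
#' Mean CV loss with one-standard-error ribbons against log lambda, with
#' the `lambda.min` and `lambda.1se` choices marked.
#'
#' @param object A [cv_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_curve <- function(object, ...) {
  lam_min <- select_lambda(object, "min")
  lam_1se <- select_lambda(object, "1se")
  ggplot2::ggplot(object, ggplot2::aes(x = log(.data$lambda), y = .data$mean_loss)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_loss - .data$se,
                                      ymax = .data$mean_loss + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(c(lam_min, lam_1se)), linetype = "dashed") +
    ggplot2::annotate("text", x = log(c(lam_min, lam_1se)), y = Inf,
                      label = c("min", "1se"), vjust = 1.5, size = 3) +
    ggplot2::labs(x = "log(lambda)", y = "mean CV loss (MSE)",
                  title = "Cross-validation over the lambda path")
}

#' Plot repeated-split MAD distributions
#'
#' One box per test set (internal held-out third, external cohort) over the
#' evaluation repeats.
#'
#' @param object A `clock_eval` from [evaluate_repeated()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clock_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(object$records, c("internal_mad", "external_mad"),
                            names_to = "test_set", values_to = "mad")
  df <- df[!is.na(df$mad), ]
  df$test_set <- sub("_mad$", "", df$test_set)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test_set, y = .data$mad)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "MAD (years)",
                  title = "Repeated-split prediction error")
}

#' Plot a batch PCA diagnostic
#'
#' Samples on the first two principal components, coloured by batch, with
#' the per-component batch F statistics in the subtitle.
#'
#' @param object A `batch_diagnostic` from [batch_pca()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.batch_diagnostic <- function(object, ...) {
  fs <- object$association
  sub <- paste(sprintf("%s: F=%.1f", fs$component[1:min(3, nrow(fs))],
                       fs$f_statistic[1:min(3, nrow(fs))]), collapse = "  ")
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$batch)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(title = "Sample PCA by batch", subtitle = sub)
}

#' Predicted versus chronological age
#'
#' @param pred A `prediction_result` from [predict_age()].
#' @param sheet Sample sheet with the chronological ages.
#' @return A ggplot with the identity line.
#' @export
plot_predictions <- function(pred, sheet) {
  sheet <- tibble::as_tibble(sheet)
  df <- dplyr::inner_join(pred, sheet[, c("sample_id", "age")], by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$predicted_age)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "chronological age (years)", y = "predicted age (years)")
}

#' @importFrom rlang .data
NULL
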