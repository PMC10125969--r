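# ggplot2 graphics for the result objects.

#' @export
autoplot.selection_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$train_auroc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$cluster_id), vjust = -0.8,
                       size = 3) +
    ggplot2::scale_x_continuous(breaks = df$step) +
    ggplot2::labs(x = "selection step", y = "training AUROC",
                  title = sprintf("Greedy forward selection (%s)",
                                  if (object$controlled) "covariates controlled"
                                  else "uncontrolled")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.histofeat_grid <- function(object, ...) {
  best <- attr(object, "best")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_selected, y = .data$tune_auroc,
                                       colour = factor(.data$K))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::annotate("point", x = best$n_selected, y = best$tune_auroc,
                      shape = 1, size = 4) +
    ggplot2::labs(x = "selected machine-learned features", y = "tune AUROC",
                  colour = "K clusters",
                  title = "Hyperparameter grid (circle = chosen configuration)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.km_fit <- function(object, ...) {
  df <- km_plot_frame(object$steps)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_low), linetype = "dashed",
                       na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_high), linetype = "dashed",
                       na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years", y = "survival") +
    ggplot2::theme_minimal()
}

km_plot_frame <- function(steps) {
  dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1, ci_low = NA_real_, ci_high = NA_real_),
    steps[, c("time", "survival", "ci_low", "ci_high")])
}

#' Kaplan-Meier risk-group curves per stage
#'
#' @param object A `risk_strat`.
#' @param ... Unused.
#' @return A ggplot: one panel per stage, low/high risk curves.
#' @export
autoplot.risk_strat <- function(object, ...) {
  rows <- list()
  for (st in names(object)) {
    for (g in names(object[[st]]$km)) {
      df <- km_plot_frame(object[[st]]$km[[g]]$steps)
      df$stage <- st
      df$group <- g
      rows[[paste(st, g)]] <- df
    }
  }
  df <- dplyr::bind_rows(rows)
  labs <- vapply(names(object), function(st)
    sprintf("%s (log-rank p = %.3g)", st, object[[st]]$logrank_p), character(1))
  df$stage <- factor(df$stage, levels = names(object), labels = labs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~stage) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years", y = "disease-specific survival",
                  colour = "risk group") +
    ggplot2::theme_minimal()
}

#' ROC curves for the predictive evaluation
#'
#' @param object An `auroc_report`.
#' @param ... Unused.
#' @return A ggplot of the clinical, combined and ML-only ROC curves.
#' @export
autoplot.auroc_report <- function(object, ...) {
  roc_frame <- function(scores, y, label) {
    ord <- order(-scores)
    tibble::tibble(
      fpr = c(0, cumsum(y[ord] == 0) / sum(y == 0)),
      tpr = c(0, cumsum(y[ord] == 1) / sum(y == 1)),
      model = label)
  }
  y <- object$scores$lnm
  df <- dplyr::bind_rows(
    roc_frame(object$scores$clinical, y, sprintf("clinical (%.3f)", object$auroc_clinical)),
    roc_frame(object$scores$combined, y, sprintf("clinical + ML (%.3f)", object$auroc_combined)),
    roc_frame(object$scores$ml_only, y, sprintf("ML only (%.3f)", object$auroc_ml_only)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity", colour = "model (AUROC)") +
    ggplot2::theme_minimal()
}
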