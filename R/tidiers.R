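# broom-style tidiers for the package's fitted objects.

#' @export
tidy.logistic_fit <- function(x, ...) {
  est <- x$coefficients
  if (!is.null(x$covariance)) {
    se <- sqrt(diag(x$covariance))
    z <- est / se
    tibble::tibble(term = names(est), estimate = unname(est),
                   std.error = unname(se), statistic = unname(z),
                   p.value = unname(2 * pnorm(-abs(z))))
  } else {
    tibble::tibble(term = names(est), estimate = unname(est),
                   std.error = NA_real_, statistic = NA_real_,
                   p.value = NA_real_)
  }
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(logLik = x$log_likelihood,
                 AIC = 2 * length(x$coefficients) - 2 * x$log_likelihood,
                 nobs = x$n, converged = x$converged, boundary = x$boundary)
}

#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(step = seq_along(x$selected_ids),
                 cluster_id = x$selected_ids,
                 train_auroc = x$step_aurocs,
                 train_loglik = x$step_logliks)
}

#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(n_selected = x$n_selected, K = x$K, controlled = x$controlled,
                 final_train_auroc = utils::tail(x$step_aurocs, 1),
                 n_skipped_fits = length(x$skipped))
}

#' @export
tidy.lrt_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 null_loglik = x$null_loglik, alt_loglik = x$alt_loglik)
}

#' @export
tidy.auroc_report <- function(x, ...) {
  tibble::tibble(
    model = c("clinical", "clinical_ml", "ml_only", "delta"),
    auroc = c(x$auroc_clinical, x$auroc_combined, x$auroc_ml_only, x$delta),
    ci_low = c(x$ci_clinical[1], x$ci_combined[1], x$ci_ml_only[1], x$ci_delta[1]),
    ci_high = c(x$ci_clinical[2], x$ci_combined[2], x$ci_ml_only[2], x$ci_delta[2]))
}

#' @export
glance.auroc_report <- function(x, ...) {
  tibble::tibble(delta = x$delta, ci_low = x$ci_delta[1],
                 ci_high = x$ci_delta[2], n_boot = x$n_boot, n_eval = x$n_eval)
}

#' @export
tidy.operating_point <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, sensitivity = x$sensitivity,
                 specificity = x$specificity, ppv = x$ppv, npv = x$npv,
                 harmonic_mean = x$harmonic_mean)
}

#' @export
tidy.km_fit <- function(x, ...) x$steps

#' @export
tidy.risk_strat <- function(x, ...) {
  rows <- list()
  for (st in names(x)) {
    s <- x[[st]]
    for (g in names(s$km)) {
      steps <- s$km[[g]]$steps
      steps$stage <- st
      steps$group <- g
      rows[[paste(st, g)]] <- steps
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
glance.risk_strat <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x), function(st) {
    s <- x[[st]]
    out <- tidyr::pivot_wider(s$five_year[, c("group", "survival", "n")],
                              names_from = "group",
                              values_from = c("survival", "n"))
    dplyr::bind_cols(tibble::tibble(stage = st,
                                    logrank_statistic = s$logrank_statistic,
                                    logrank_p = s$logrank_p), out)
  }))
}

#' @export
tidy.confound_check <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble::tibble(p_value = rep(x$p_value, nrow(x$summary)),
                                  flag = rep(x$flag, nrow(x$summary))))
}
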