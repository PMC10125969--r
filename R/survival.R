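# Risk-group construction and disease-specific survival analysis:
# ML-feature-only risk scores, median-score thresholding over an accrual
# window, Kaplan-Meier estimation (Greenwood variance, log-log CIs via the
# survival package), log-rank tests and per-stage risk stratification.

#' Fit a risk-scoring model on the ML features alone
#'
#' Logistic model on the selected clusters' quantitation fractions only,
#' trained on the development records. The target is the LNM label by
#' default; a disease-specific-death target (`dss_event`) is also offered,
#' since risk stratification may reasonably be anchored to either endpoint.
#'
#' @param dev_records Development-split case records.
#' @param dev_quants Quantitation table for the development records.
#' @param ml_ids Selected cluster ids (nonempty).
#' @param target `"lnm"` (default) or `"dss_event"`.
#' @return A `risk_model`; score new cases with [predict.risk_model()].
#' @export
risk_scores <- function(dev_records, dev_quants, ml_ids,
                        target = c("lnm", "dss_event")) {
  target <- match.arg(target)
  ml_ids <- as.integer(ml_ids)
  if (length(ml_ids) == 0L) abort("`ml_ids` must be nonempty.")
  y <- if (target == "lnm") dev_records$lnm else dev_records$event
  if (is.null(y) || anyNA(y)) abort(sprintf("target `%s` unavailable for all records.", target))
  x <- quant_matrix(dev_quants, dev_records$case_id, ml_ids)
  fit <- fit_logistic(x, as_binary01(y, target))
  if (!fit$converged) abort("risk-score model did not converge.")
  structure(list(fit = fit, ml_ids = ml_ids, target = target),
            class = "risk_model")
}

#' Score cases with a fitted risk model
#'
#' @param object A `risk_model`.
#' @param records Case records to score.
#' @param quants Quantitation table covering `records`.
#' @param ... Unused.
#' @return Tibble `case_id`, `score` (predicted probability).
#' @export
predict.risk_model <- function(object, records, quants, ...) {
  x <- quant_matrix(quants, records$case_id, object$ml_ids)
  tibble::tibble(case_id = records$case_id,
                 score = predict(object$fit, x))
}

#' Median score over an accrual-year window
#'
#' The risk-group threshold: the median model score among cases accrued in
#' the given window (the "most recent years of the development cohort"
#' rule). Even case counts take the mean of the two middle scores.
#'
#' @param records Case records with `accrual_year`.
#' @param scores Numeric scores aligned with `records`, or a tibble
#'   (`case_id`, `score`).
#' @param year_window Integer interval `c(first, last)`, inclusive.
#' @return The median score (scalar).
#' @export
median_threshold <- function(records, scores, year_window) {
  if (is.data.frame(scores)) {
    scores <- scores$score[match(records$case_id, scores$case_id)]
  }
  stopifnot(length(scores) == nrow(records))
  in_win <- !is.na(records$accrual_year) &
    records$accrual_year >= year_window[1] &
    records$accrual_year <= year_window[2]
  if (!any(in_win)) {
    abort(sprintf("no cases accrued in [%d, %d].", year_window[1], year_window[2]))
  }
  median(scores[in_win])
}

#' Kaplan-Meier estimate with Greenwood confidence intervals
#'
#' Product-limit estimator of the survival function under right censoring,
#' with Greenwood variance and log-log transformed 95% intervals (computed
#' via `survival::survfit`). Deaths precede censorings at tied times.
#'
#' @param times Nonnegative follow-up times.
#' @param events 0/1 event indicators (1 = death).
#' @param conf_level Confidence level.
#' @return A `km_fit`: tibble `steps` (`time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `ci_low`, `ci_high`) plus `n`. Evaluate at
#'   arbitrary times with [km_survival()].
#' @export
km_estimate <- function(times, events, conf_level = 0.95) {
  if (any(times < 0)) abort("negative survival times.")
  events <- as_binary01(events, "events")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "log-log", conf.int = conf_level)
  steps <- tibble::tibble(time = sf$time, n_risk = sf$n.risk,
                          n_event = sf$n.event, n_censor = sf$n.censor,
                          survival = sf$surv,
                          ci_low = ifelse(is.na(sf$lower), NA_real_, sf$lower),
                          ci_high = ifelse(is.na(sf$upper), NA_real_, sf$upper))
  structure(list(steps = steps, n = length(times)), class = "km_fit")
}

#' Evaluate a Kaplan-Meier step function
#'
#' Right-continuous step lookup: S(t) is 1 before the first event and holds
#' its last value beyond the final observed time.
#'
#' @param km A `km_fit`.
#' @param t Times at which to evaluate.
#' @return Survival probabilities.
#' @export
km_survival <- function(km, t) {
  st <- km$steps[km$steps$n_event > 0L | km$steps$n_censor > 0L, ]
  f <- stats::stepfun(km$steps$time, c(1, km$steps$survival), right = FALSE)
  f(t)
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n = %d, %d event times, final S = %.3f\n",
              x$n, sum(x$steps$n_event > 0), min(1, utils::tail(x$steps$survival, 1))))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard chi-square log-rank comparison of two survival curves (1 df),
#' via `survival::survdiff`.
#'
#' @param times_a,events_a First group's follow-up times and 0/1 events.
#' @param times_b,events_b Second group.
#' @return List `statistic`, `p_value`.
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L) {
    abort("both groups must be nonempty.")
  }
  times <- c(times_a, times_b)
  events <- as_binary01(c(events_a, events_b), "events")
  grp <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  if (sum(events) == 0L) return(list(statistic = 0, p_value = 1))
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  list(statistic = unname(sd$chisq),
       p_value = pchisq(unname(sd$chisq), df = 1L, lower.tail = FALSE))
}

#' Per-stage Kaplan-Meier risk stratification
#'
#' Within each stage (node-negative cases as the stage II analog,
#' node-positive as stage III), cases are split at the supplied score
#' threshold (score >= threshold = high risk), Kaplan-Meier curves are
#' estimated per group, the groups are compared with a log-rank test, and
#' survival at the horizon is reported with confidence intervals. When the
#' horizon falls beyond a group's last observed time, the last step value is
#' reported and the group is listed in `horizon_caveats`.
#'
#' @param records Case records with `lnm`, `survival_time`, `event`.
#' @param scores Numeric scores aligned with `records`, or a tibble
#'   (`case_id`, `score`).
#' @param threshold Risk-group threshold (e.g. from [median_threshold()]).
#' @param horizon_years Reporting horizon (default 5).
#' @return A `risk_strat`: per-stage list with `km` fits per group,
#'   `logrank_statistic`, `logrank_p`, and a `five_year` tibble (group,
#'   survival, ci_low, ci_high, n).
#' @export
stratified_km_report <- function(records, scores, threshold,
                                 horizon_years = 5) {
  if (is.data.frame(scores)) {
    scores <- scores$score[match(records$case_id, scores$case_id)]
  }
  stopifnot(length(scores) == nrow(records))
  if (is.null(records[["survival_time"]]) || anyNA(records$survival_time)) {
    abort("all records need survival data for risk stratification.")
  }
  stages <- list("stage II" = records$lnm == 0L, "stage III" = records$lnm == 1L)
  out <- list()
  for (st in names(stages)) {
    keep <- stages[[st]]
    if (!any(keep)) abort(sprintf("no cases in %s.", st))
    rec <- records[keep, , drop = FALSE]
    sc <- scores[keep]
    group <- ifelse(sc >= threshold, "high", "low")
    if (length(unique(group)) < 2L) {
      abort(sprintf("%s: a risk group is empty at this threshold.", st))
    }
    kms <- list()
    fy <- list()
    caveats <- character(0)
    for (g in c("low", "high")) {
      idx <- group == g
      km <- km_estimate(rec$survival_time[idx], rec$event[idx])
      kms[[g]] <- km
      last_t <- max(km$steps$time)
      t_eval <- min(horizon_years, last_t)
      if (horizon_years > last_t) caveats <- c(caveats, g)
      # CI at the horizon: last step at or before t_eval
      at <- km$steps[km$steps$time <= t_eval & km$steps$n_event > 0L, ]
      if (nrow(at) == 0L) {
        fy[[g]] <- tibble::tibble(group = g, survival = 1, ci_low = NA_real_,
                                  ci_high = NA_real_, n = sum(idx))
      } else {
        last <- at[nrow(at), ]
        fy[[g]] <- tibble::tibble(group = g, survival = last$survival,
                                  ci_low = last$ci_low, ci_high = last$ci_high,
                                  n = sum(idx))
      }
    }
    lr <- logrank(rec$survival_time[group == "low"], rec$event[group == "low"],
                  rec$survival_time[group == "high"], rec$event[group == "high"])
    out[[st]] <- list(stage_label = st, threshold = threshold,
                      groups = tibble::tibble(case_id = rec$case_id, group = group),
                      km = kms, logrank_statistic = lr$statistic,
                      logrank_p = lr$p_value,
                      five_year = dplyr::bind_rows(fy),
                      horizon_years = horizon_years,
                      horizon_caveats = caveats)
  }
  structure(out, class = "risk_strat")
}

#' @export
print.risk_strat <- function(x, ...) {
  for (st in names(x)) {
    s <- x[[st]]
    cat(sprintf("%s: log-rank chi-square = %.3f, p = %.3g\n",
                st, s$logrank_statistic, s$logrank_p))
    fy <- s$five_year
    for (i in seq_len(nrow(fy))) {
      cat(sprintf("  %4s risk (n = %d): %g-year survival %.3f [%.3f, %.3f]%s\n",
                  fy$group[i], fy$n[i], s$horizon_years, fy$survival[i],
                  fy$ci_low[i], fy$ci_high[i],
                  if (fy$group[i] %in% s$horizon_caveats)
                    " (last observed time precedes horizon)" else ""))
    }
  }
  invisible(x)
}
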