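# Statistical evaluation of the selected machine-learned features: AUROC
# (Mann-Whitney), bootstrap CIs, nested-model likelihood-ratio test,
# multivariable odds ratios, predictive AUROC gain, operating point,
# univariable per-feature statistics and the batch-confound check.

#' Area under the ROC curve (Mann-Whitney)
#'
#' Probability that a random positive case outscores a random negative one,
#' ties counting one half. Invariant under any strictly monotone transform
#' of the scores.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- as_binary01(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present.")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired bootstrap confidence intervals for two AUROCs and their difference
#'
#' Case-level resampling with replacement, jointly for both score vectors
#' (the same resampled cases score both models, so the difference is
#' paired). Percentile 2.5/97.5 intervals. Resamples containing a single
#' class are redrawn and counted in `n_redrawn`.
#'
#' @param scores_a,scores_b Score vectors for the two models, aligned with
#'   `labels`.
#' @param labels 0/1 labels.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `auroc_a`, `auroc_b`, `delta` point estimates, matching
#'   `ci_*` intervals, `n_boot`, `seed`, `n_redrawn`.
#' @export
bootstrap_auroc_ci <- function(scores_a, scores_b, labels, n_boot = 1000L,
                               seed = 1L, conf_level = 0.95) {
  n_boot <- assert_count(n_boot, "n_boot")
  y <- as_binary01(labels)
  n <- length(y)
  stopifnot(length(scores_a) == n, length(scores_b) == n)
  alpha <- (1 - conf_level) / 2
  boot_a <- boot_b <- numeric(n_boot)
  n_redrawn <- 0L
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
        n_redrawn <- n_redrawn + 1L
      }
      boot_a[b] <- auroc(scores_a[idx], y[idx])
      boot_b[b] <- auroc(scores_b[idx], y[idx])
    }
  })
  probs <- c(alpha, 1 - alpha)
  list(auroc_a = auroc(scores_a, y), auroc_b = auroc(scores_b, y),
       delta = auroc(scores_b, y) - auroc(scores_a, y),
       ci_a = unname(quantile(boot_a, probs)),
       ci_b = unname(quantile(boot_b, probs)),
       ci_delta = unname(quantile(boot_b - boot_a, probs)),
       n_boot = n_boot, seed = as.integer(seed), n_redrawn = n_redrawn)
}

#' Likelihood-ratio test for the added value of ML features
#'
#' Fits a null logistic model (baseline clinicopathologic covariates only)
#' and an alternative model (covariates plus the quantitation fractions of
#' `ml_ids`) on the SAME records — this is the analytical evaluation path,
#' fit on the evaluation set itself — and compares them with a chi-square
#' likelihood-ratio test on `length(ml_ids)` degrees of freedom.
#'
#' @param records Evaluation-set case records.
#' @param quants Quantitation table.
#' @param ml_ids Integer cluster ids added in the alternative model.
#' @param baseline_spec Optional [design_spec()] for the covariate block.
#' @return An `lrt_result`: `statistic`, `df`, `p_value`, `null_loglik`,
#'   `alt_loglik`.
#' @export
likelihood_ratio_test <- function(records, quants, ml_ids,
                                  baseline_spec = NULL) {
  ml_ids <- as.integer(ml_ids)
  spec0 <- baseline_spec %||% design_spec(records)
  null_fit <- fit_logistic(encode_design(records, spec0))
  if (length(ml_ids) == 0L) {
    return(structure(list(statistic = 0, df = 0L, p_value = 1,
                          null_loglik = null_fit$log_likelihood,
                          alt_loglik = null_fit$log_likelihood),
                     class = "lrt_result"))
  }
  spec1 <- design_spec(records, ml_feature_ids = ml_ids,
                       covariates = names(spec0$layout))
  alt_fit <- fit_logistic(encode_design(records, spec1, quants))
  if (!null_fit$converged || !alt_fit$converged) {
    abort("likelihood-ratio test requires both fits to converge.")
  }
  stat <- max(0, 2 * (alt_fit$log_likelihood - null_fit$log_likelihood))
  structure(list(statistic = stat, df = length(ml_ids),
                 p_value = pchisq(stat, df = length(ml_ids), lower.tail = FALSE),
                 null_loglik = null_fit$log_likelihood,
                 alt_loglik = alt_fit$log_likelihood),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: chi-square = %.4f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Odds-ratio table from a multivariable logistic fit
#'
#' Exponentiated coefficients with Wald 95% confidence intervals and
#' p-values, one row per design column plus an `OR = 1.00` row for every
#' reference level (reported without CI, matching standard multivariable OR
#' tables).
#'
#' @param fit A converged `logistic_fit`.
#' @param spec The [design_spec()] the fit was encoded with.
#' @param conf_level Confidence level for the Wald intervals.
#' @return Tibble: `term`, `level`, `reference`, `estimate` (log-odds),
#'   `or`, `ci_low`, `ci_high`, `p_value`.
#' @export
odds_ratio_table <- function(fit, spec, conf_level = 0.95) {
  if (!inherits(fit, "logistic_fit")) abort("`fit` must be a logistic_fit.")
  if (!fit$converged) abort("odds ratios require a converged fit.")
  v <- fit$covariance %||% abort("fit carries no covariance matrix.")
  z <- qnorm(1 - (1 - conf_level) / 2)
  rows <- list()
  add_row <- function(term, level, col) {
    if (is.na(col)) {  # reference level
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        term = term, level = level, reference = TRUE, estimate = 0,
        or = 1, ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_)
    } else {
      b <- fit$coefficients[[col]]
      se <- sqrt(v[col, col])
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        term = term, level = level, reference = FALSE, estimate = b,
        or = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se),
        p_value = 2 * pnorm(-abs(b / se)))
    }
  }
  for (nm in names(spec$layout)) {
    lay <- spec$layout[[nm]]
    if (length(lay$levels) > 0L) add_row(nm, lay$ref, NA_character_)
    for (i in seq_along(lay$cols)) add_row(nm, lay$levels[i + 1L], lay$cols[i])
  }
  for (id in spec$ml_feature_ids) {
    add_row("ml_feature", quant_col(id), quant_col(id))
  }
  dplyr::bind_rows(rows)
}

#' Predictive evaluation: AUROC gain from adding ML features
#'
#' Fits three logistic models on the training records — clinical-only,
#' clinical + ML, and ML-only — scores the evaluation records with each, and
#' reports the three AUROCs, the clinical-vs-combined delta, and paired
#' bootstrap confidence intervals. Train and evaluation case ids must be
#' disjoint (leakage guard; this path never refits on evaluation data).
#'
#' @param train_records,eval_records Disjoint case record tibbles.
#' @param quants Quantitation table covering both splits.
#' @param ml_ids Selected cluster ids.
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @param baseline_spec Optional [design_spec()] for the covariate block.
#' @return An `auroc_report`: `auroc_clinical`, `auroc_combined`,
#'   `auroc_ml_only`, `delta`, `ci_*` intervals, `n_boot`, `seed`, `n_eval`.
#' @export
predictive_evaluation <- function(train_records, eval_records, quants, ml_ids,
                                  n_boot = 1000L, seed = 1L,
                                  baseline_spec = NULL) {
  overlap <- intersect(train_records$case_id, eval_records$case_id)
  if (length(overlap) > 0L) {
    abort(sprintf("train/eval splits overlap (%d shared case ids, e.g. %s); refusing to evaluate.",
                  length(overlap), overlap[1L]))
  }
  ml_ids <- as.integer(ml_ids)
  spec_clin <- baseline_spec %||% design_spec(train_records)
  spec_comb <- design_spec(train_records, ml_feature_ids = ml_ids,
                           covariates = names(spec_clin$layout))
  spec_ml <- design_spec(train_records, ml_feature_ids = ml_ids,
                         covariates = character(0))

  fit_clin <- fit_logistic(encode_design(train_records, spec_clin))
  fit_comb <- fit_logistic(encode_design(train_records, spec_comb, quants))
  fit_ml <- fit_logistic(encode_design(train_records, spec_ml, quants))

  s_clin <- predict(fit_clin, encode_design(eval_records, spec_clin))
  s_comb <- predict(fit_comb, encode_design(eval_records, spec_comb, quants))
  s_ml <- predict(fit_ml, encode_design(eval_records, spec_ml, quants))
  y <- as_binary01(eval_records$lnm, "lnm")

  bt <- bootstrap_auroc_ci(s_clin, s_comb, y, n_boot = n_boot, seed = seed)
  bt_ml <- bootstrap_auroc_ci(s_ml, s_ml, y, n_boot = n_boot, seed = seed)

  structure(list(auroc_clinical = bt$auroc_a, auroc_combined = bt$auroc_b,
                 auroc_ml_only = auroc(s_ml, y), delta = bt$delta,
                 ci_clinical = bt$ci_a, ci_combined = bt$ci_b,
                 ci_delta = bt$ci_delta, ci_ml_only = bt_ml$ci_a,
                 n_boot = bt$n_boot, seed = bt$seed,
                 n_eval = length(y),
                 scores = tibble::tibble(case_id = eval_records$case_id,
                                         clinical = s_clin, combined = s_comb,
                                         ml_only = s_ml, lnm = y),
                 fits = list(clinical = fit_clin, combined = fit_comb,
                             ml_only = fit_ml),
                 specs = list(clinical = spec_clin, combined = spec_comb,
                              ml_only = spec_ml)),
            class = "auroc_report")
}

#' @export
print.auroc_report <- function(x, ...) {
  fmt <- function(a, ci) sprintf("%.3f [%.3f, %.3f]", a, ci[1], ci[2])
  cat("AUROC for LNM prediction (bootstrap 95% CI)\n")
  cat("  Clinical      ", fmt(x$auroc_clinical, x$ci_clinical), "\n")
  cat("  Clinical + ML ", fmt(x$auroc_combined, x$ci_combined), "\n")
  cat("  ML only       ", fmt(x$auroc_ml_only, x$ci_ml_only), "\n")
  cat("  Delta         ", fmt(x$delta, x$ci_delta), "\n")
  invisible(x)
}

#' Operating point maximizing the harmonic mean of sensitivity and specificity
#'
#' Scans thresholds at midpoints between consecutive distinct score values
#' (plus outer sentinels) with prediction rule `score >= threshold`, and
#' returns the threshold maximizing the harmonic mean of sensitivity and
#' specificity (ties: lower threshold), with sensitivity, specificity, PPV
#' and NPV at that cut. PPV/NPV are `NA` when no case is predicted
#' positive/negative.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return An `operating_point`: `threshold`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `harmonic_mean`.
#' @export
operating_point <- function(scores, labels) {
  y <- as_binary01(labels)
  if (length(unique(y)) < 2L) abort("both classes must be present.")
  s <- sort(unique(scores))
  thr <- if (length(s) == 1L) s else (s[-length(s)] + s[-1L]) / 2
  thr <- c(min(s) - 1, thr)  # sentinel: everything predicted positive
  best <- NULL
  for (t in thr) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
    fn <- sum(pred == 0L & y == 1L); tn <- sum(pred == 0L & y == 0L)
    se <- tp / (tp + fn); sp <- tn / (tn + fp)
    hm <- if (se + sp == 0) 0 else 2 * se * sp / (se + sp)
    if (is.null(best) || hm > best$harmonic_mean + 1e-12) {
      best <- list(threshold = t, sensitivity = se, specificity = sp,
                   ppv = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
                   npv = if (tn + fn > 0L) tn / (tn + fn) else NA_real_,
                   harmonic_mean = hm)
    }
  }
  structure(best, class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(paste0("Operating point (max harmonic mean of Se/Sp): threshold %.4g\n",
                     "  Se %.3f  Sp %.3f  PPV %.3f  NPV %.3f\n"),
              x$threshold, x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Univariable statistics for a single machine-learned feature
#'
#' AUROC of the cluster's quantitation fraction used directly as a score,
#' and the odds ratio (with Wald CI) from a univariable logistic fit.
#'
#' @param records Case records.
#' @param quants Quantitation table.
#' @param ml_id Single cluster id.
#' @return Tibble: `ml_id`, `auroc`, `or`, `ci_low`, `ci_high`, `p_value`.
#' @export
univariable_feature_stats <- function(records, quants, ml_id) {
  ml_id <- assert_count(ml_id, "ml_id")
  f <- drop(quant_matrix(quants, records$case_id, ml_id))
  if (length(unique(f)) < 2L) abort("feature is constant; no univariable statistics.")
  y <- as_binary01(records$lnm, "lnm")
  x <- matrix(f, ncol = 1L, dimnames = list(NULL, quant_col(ml_id)))
  fit <- fit_logistic(x, y)
  if (fit$converged) {
    ort <- odds_ratio_table(fit, structure(list(layout = list(),
                                                ml_feature_ids = ml_id,
                                                dropped_levels = character(0)),
                                           class = "design_spec"))
    or_row <- ort[1L, c("or", "ci_low", "ci_high", "p_value")]
  } else {
    # a perfectly separating feature has no finite ML odds ratio
    warn(sprintf("univariable fit for cluster %d did not converge (separation); OR reported as NA.",
                 ml_id))
    or_row <- tibble::tibble(or = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_, p_value = NA_real_)
  }
  tibble::tibble(ml_id = ml_id, auroc = auroc(f, y),
                 or = or_row$or, ci_low = or_row$ci_low,
                 ci_high = or_row$ci_high, p_value = or_row$p_value)
}

#' Batch confound check on model scores
#'
#' Compares model scores across batches among label-negative cases only: if
#' negatives score systematically differently by batch, the model has likely
#' learned a batch artifact (the scan-date failure mode) rather than
#' biology. Two batches are compared with a two-sided Wilcoxon rank-sum
#' test; more with a Kruskal-Wallis test.
#'
#' @param records Case records with a batch column.
#' @param scores Numeric scores aligned with `records`, or a tibble
#'   (`case_id`, `score`).
#' @param batch_key Name of the batch column (default `"batch"`).
#' @param alpha Flagging level (default 0.01).
#' @return A `confound_check`: per-batch summary tibble, `p_value`, `flag`.
#' @export
batch_confound_check <- function(records, scores, batch_key = "batch",
                                 alpha = 0.01) {
  if (is.data.frame(scores)) {
    scores <- scores$score[match(records$case_id, scores$case_id)]
  }
  stopifnot(length(scores) == nrow(records))
  batch <- records[[batch_key]]
  if (is.null(batch)) abort(sprintf("no `%s` column in records.", batch_key))
  if (length(unique(batch)) < 2L) abort("need at least 2 batches.")
  neg <- records$lnm == 0L
  s <- scores[neg]
  b <- factor(batch[neg])
  if (any(table(b) == 0L)) {
    abort("a batch has no label-negative cases; confound check undefined.")
  }
  p <- if (nlevels(b) == 2L) {
    suppressWarnings(wilcox.test(s ~ b)$p.value)
  } else {
    kruskal.test(s, b)$p.value
  }
  summary_tbl <- tibble::tibble(
    batch = levels(b),
    n_negative = as.integer(table(b)),
    mean_score = as.numeric(tapply(s, b, mean)))
  structure(list(summary = summary_tbl, p_value = p, alpha = alpha,
                 flag = is.finite(p) && p < alpha),
            class = "confound_check")
}

#' @export
print.confound_check <- function(x, ...) {
  cat(sprintf("Batch confound check (label-negative cases): p = %.3g — %s\n",
              x$p_value,
              if (x$flag) "FLAGGED: scores differ by batch" else "no flag"))
  print(x$summary)
  invisible(x)
}
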