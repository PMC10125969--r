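# Covariate encoding, unpenalized logistic fits and greedy forward selection
# of cluster features with the baseline clinicopathologic covariates held in
# the model at every step (controlled mode) or absent (uncontrolled
# negative-control mode).

#' Design specification for the LNM logistic models
#'
#' Fixes the indicator layout: one column per non-reference covariate level
#' (reference levels: age <60, male sex, grade G1, the lowest T-category
#' present in `records`, L0, V0), followed by the selected clusters'
#' quantitation fractions. Levels absent from `records` are dropped from the
#' layout and recorded in `dropped_levels`.
#'
#' @param records Tibble of case records used to fit (defines which levels
#'   are present).
#' @param ml_feature_ids Ordered integer cluster ids appended after the
#'   covariate columns (may be empty).
#' @param covariates Covariate names to include; defaults to all six baseline
#'   clinicopathologic variables. Use `character(0)` for an ML-only design.
#' @return A `design_spec`.
#' @export
design_spec <- function(records, ml_feature_ids = integer(0),
                        covariates = covariate_names()) {
  lv <- covariate_levels()[covariates]
  layout <- list()
  dropped <- character(0)
  for (nm in names(lv)) {
    bad <- setdiff(unique(records[[nm]]), lv[[nm]])
    if (length(bad) > 0L) {
      abort(sprintf("unseen %s level(s): %s", nm, paste(bad, collapse = ", ")))
    }
    present <- lv[[nm]][lv[[nm]] %in% unique(records[[nm]])]
    absent <- setdiff(lv[[nm]], present)
    if (length(absent) > 0L) {
      dropped <- c(dropped, paste(nm, absent, sep = "_"))
    }
    if (length(present) <= 1L) {
      layout[[nm]] <- list(ref = present, cols = character(0), levels = present)
    } else {
      layout[[nm]] <- list(ref = present[1L],
                           cols = paste(nm, present[-1L], sep = "_"),
                           levels = present)
    }
  }
  structure(list(layout = layout, ml_feature_ids = as.integer(ml_feature_ids),
                 dropped_levels = dropped),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>\n")
  for (nm in names(x$layout)) {
    cat(sprintf("  %s: ref %s | %s\n", nm, x$layout[[nm]]$ref,
                paste(x$layout[[nm]]$cols, collapse = ", ")))
  }
  if (length(x$ml_feature_ids) > 0)
    cat("  ML features:", paste(x$ml_feature_ids, collapse = ", "), "\n")
  if (length(x$dropped_levels) > 0)
    cat("  dropped (absent from fitting data):",
        paste(x$dropped_levels, collapse = ", "), "\n")
  invisible(x)
}

design_colnames <- function(spec) {
  c(unlist(lapply(spec$layout, `[[`, "cols"), use.names = FALSE),
    quant_col(spec$ml_feature_ids))
}

#' Encode case records into a design matrix and label vector
#'
#' One row per case: indicator columns for non-reference covariate levels in
#' the spec's layout, then the quantitation fractions of the spec's ML
#' feature ids. A record at all reference levels with no ML features encodes
#' to an all-zero row.
#'
#' @param records Tibble of case records.
#' @param spec A [design_spec()].
#' @param quants Quantitation table (`case_id`, `cl_1..cl_K`); required when
#'   the spec carries ML feature ids.
#' @return List with `x` (numeric matrix, named columns), `y` (0/1 integer
#'   labels) and `case_id`.
#' @export
encode_design <- function(records, spec, quants = NULL) {
  if (!inherits(spec, "design_spec")) abort("`spec` must be a design_spec.")
  n <- nrow(records)
  blocks <- list()
  for (nm in names(spec$layout)) {
    lay <- spec$layout[[nm]]
    vals <- records[[nm]]
    bad <- setdiff(unique(vals), lay$levels)
    if (length(bad) > 0L) {
      abort(sprintf("unseen %s level(s) at encode time: %s",
                    nm, paste(bad, collapse = ", ")))
    }
    if (length(lay$cols) == 0L) next
    m <- vapply(lay$levels[-1L], function(l) as.numeric(vals == l), numeric(n))
    m <- matrix(m, nrow = n, dimnames = list(NULL, lay$cols))
    blocks[[nm]] <- m
  }
  x <- if (length(blocks) > 0L) do.call(cbind, blocks) else
    matrix(numeric(0), nrow = n, ncol = 0L)
  if (length(spec$ml_feature_ids) > 0L) {
    if (is.null(quants)) abort("`quants` required when the spec has ML feature ids.")
    x <- cbind(x, quant_matrix(quants, records$case_id, spec$ml_feature_ids))
  }
  colnames(x) <- design_colnames(spec)
  rownames(x) <- NULL
  list(x = x, y = as_binary01(records$lnm, "lnm"), case_id = records$case_id)
}

# Fast unpenalized logistic fit on a bare matrix (intercept added here).
# Returns coefficients, fitted probabilities, log-likelihood, convergence
# and a boundary (separation) flag. Covariance is computed on demand.
logit_fit_matrix <- function(x, y, epsilon = 1e-8, maxit = 100L) {
  xi <- cbind(`(Intercept)` = 1, x)
  boundary <- FALSE
  fit <- withCallingHandlers(
    glm.fit(xi, y, family = binomial(),
            control = list(epsilon = epsilon, maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        boundary <<- TRUE
      invokeRestart("muffleWarning")
    })
  p <- fit$fitted.values
  # complete separation: the training data are perfectly classified with
  # boundary probabilities, even when IRLS reports formal convergence
  # (coefficients on fraction-scale features are legitimately large, so the
  # check is on fitted probabilities, not coefficient magnitude)
  if (all(ifelse(y == 1L, p > 1 - 1e-6, p < 1e-6))) boundary <- TRUE
  eps <- .Machine$double.eps
  ll <- sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  list(coefficients = fit$coefficients, fitted = p, log_likelihood = ll,
       converged = isTRUE(fit$converged) && !boundary,
       boundary = boundary, x = xi, y = y, n = length(y))
}

# Inverse observed information. Columns aliased by glm.fit (NA coefficient,
# e.g. under exact collinearity) get NA rows/columns rather than failing.
logit_covariance <- function(fit) {
  keep <- !is.na(fit$coefficients)
  w <- fit$fitted * (1 - fit$fitted)
  xtwx <- crossprod(fit$x[, keep, drop = FALSE] * sqrt(w))
  vk <- tryCatch(chol2inv(chol(xtwx)), error = function(e) {
    abort("information matrix is not positive definite; model covariance unavailable.")
  })
  p <- length(fit$coefficients)
  v <- matrix(NA_real_, p, p,
              dimnames = list(colnames(fit$x), colnames(fit$x)))
  v[keep, keep] <- vk
  v
}

#' Fit an unpenalized multivariable logistic regression
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' (convergence tolerance 1e-8 on the deviance scale). Complete or
#' quasi-complete separation is reported honestly as a non-converged fit
#' (`converged = FALSE`, `boundary = TRUE`) rather than silently returning
#' divergent coefficients.
#'
#' @param design Either the list returned by [encode_design()] or a numeric
#'   design matrix (without intercept column).
#' @param labels 0/1 labels; ignored when `design` carries `y`.
#' @return A `logistic_fit` with `coefficients` (incl. intercept),
#'   `covariance`, `log_likelihood`, `fitted`, `converged`, `n`.
#' @export
fit_logistic <- function(design, labels = NULL) {
  if (is.list(design) && !is.null(design$x)) {
    x <- design$x
    y <- design$y
  } else {
    x <- as.matrix(design)
    y <- as_binary01(labels)
  }
  if (length(unique(y)) < 2L) abort("need at least one case in each class.")
  raw <- logit_fit_matrix(x, y)
  cov <- if (raw$converged) logit_covariance(raw) else NULL
  structure(list(coefficients = raw$coefficients, covariance = cov,
                 log_likelihood = raw$log_likelihood, fitted = raw$fitted,
                 converged = raw$converged, boundary = raw$boundary,
                 n = raw$n, terms = colnames(raw$x)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, logLik = %.4f, converged = %s%s\n",
              x$n, x$log_likelihood, x$converged,
              if (x$boundary) " (separation)" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict probabilities from a logistic fit
#'
#' @param object A `logistic_fit`.
#' @param newdata Design matrix with the same columns the fit was trained on
#'   (without intercept), or an [encode_design()] list.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata) && !is.null(newdata$x)) newdata$x else as.matrix(newdata)
  eta <- drop(cbind(1, x) %*% object$coefficients)
  plogis(eta)
}

#' Greedy forward selection of cluster features
#'
#' Iteratively adds the candidate cluster whose quantitation fraction gives
#' the largest increase in training-set AUROC when added to the logistic
#' model. In controlled mode (the default, and the pipeline's primary mode)
#' the baseline clinicopathologic covariates are in the design at every
#' step; in uncontrolled mode (negative control) the design holds only the
#' ML features accrued so far. AUROC ties are broken by lowest cluster id.
#' Candidates whose fit fails to converge at a step are skipped (logged via
#' `skipped`).
#'
#' @param records Training-split case records.
#' @param quants Quantitation table covering all `records`.
#' @param candidate_ids Integer cluster ids to select among.
#' @param n_select Number of features to select.
#' @param controlled Keep the baseline covariates in the model throughout?
#' @param baseline_spec Optional [design_spec()] for the covariate block;
#'   defaults to all six baseline covariates as observed in `records`.
#' @return A `selection_result`: `selected_ids`, per-step `step_aurocs` and
#'   `step_logliks`, `controlled`, `K`, `n_selected`, `skipped`.
#' @export
greedy_forward_select <- function(records, quants, candidate_ids, n_select,
                                  controlled = TRUE, baseline_spec = NULL) {
  n_select <- assert_count(n_select, "n_select")
  candidate_ids <- as.integer(candidate_ids)
  if (anyDuplicated(candidate_ids)) abort("`candidate_ids` must be distinct.")
  if (n_select > length(candidate_ids)) {
    abort("`n_select` exceeds the number of candidate features.")
  }
  y <- as_binary01(records$lnm, "lnm")
  if (length(unique(y)) < 2L) abort("training records must contain both classes.")

  if (controlled) {
    spec0 <- baseline_spec %||% design_spec(records)
    x_base <- encode_design(records, spec0)$x
  } else {
    x_base <- matrix(numeric(0), nrow = nrow(records), ncol = 0L)
  }
  q_all <- quant_matrix(quants, records$case_id, candidate_ids)

  selected <- integer(0)
  step_aurocs <- numeric(0)
  step_logliks <- numeric(0)
  skipped <- list()
  remaining <- candidate_ids

  for (step in seq_len(n_select)) {
    best_auc <- -Inf
    best_id <- NA_integer_
    best_ll <- NA_real_
    x_cur <- cbind(x_base, q_all[, quant_col(selected), drop = FALSE])
    for (id in remaining) {
      xc <- cbind(x_cur, q_all[, quant_col(id), drop = FALSE])
      fit <- logit_fit_matrix(xc, y)
      if (!fit$converged) {
        skipped[[length(skipped) + 1L]] <- list(step = step, id = id)
        next
      }
      auc <- auroc(fit$fitted, y)
      if (auc > best_auc + 1e-12 ||
          (abs(auc - best_auc) <= 1e-12 && id < best_id)) {
        best_auc <- auc
        best_id <- id
        best_ll <- fit$log_likelihood
      }
    }
    if (is.na(best_id)) {
      abort(sprintf("no candidate fit converged at step %d.", step))
    }
    selected <- c(selected, best_id)
    step_aurocs <- c(step_aurocs, best_auc)
    step_logliks <- c(step_logliks, best_ll)
    remaining <- setdiff(remaining, best_id)
  }

  structure(list(selected_ids = selected, step_aurocs = step_aurocs,
                 step_logliks = step_logliks, controlled = controlled,
                 K = quant_K(quants), n_selected = n_select,
                 skipped = skipped),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s, K = %d\n",
              if (x$controlled) "controlled" else "uncontrolled (negative control)",
              x$K))
  print(tidy(x))
  invisible(x)
}

#' Hyperparameter grid over K and feature count
#'
#' For each candidate cluster count `K`, runs greedy selection on the
#' training split and evaluates the combined (covariates + selected
#' clusters) model's AUROC on the tune split at every prefix length
#' `1..max(n_grid)`. The configuration maximizing tune AUROC (ties: smaller
#' K, then smaller n) is recorded as `best`.
#'
#' @param records Case records containing `train` and `tune` splits.
#' @param quants_by_K Named list mapping K (as character or via names) to the
#'   quantitation table produced with that K.
#' @param K_grid Cluster counts to evaluate (default 10, 25, 50, 100, 200).
#' @param n_grid Feature counts to evaluate (default 1..10).
#' @param controlled Passed to [greedy_forward_select()].
#' @return A `histofeat_grid` tibble with columns `K`, `n_selected`,
#'   `tune_auroc`; attributes `best` (list) and `selections` (per-K
#'   selection results).
#' @export
hyperparameter_grid <- function(records, quants_by_K,
                                K_grid = c(10L, 25L, 50L, 100L, 200L),
                                n_grid = 1:10, controlled = TRUE) {
  for (s in c("train", "tune")) {
    if (!any(records$split == s)) abort(sprintf("missing `%s` split.", s))
  }
  train <- records[records$split == "train", , drop = FALSE]
  tune <- records[records$split == "tune", , drop = FALSE]
  spec0 <- design_spec(train)
  n_max <- max(n_grid)
  rows <- list()
  selections <- list()
  for (K in K_grid) {
    quants <- quants_by_K[[as.character(K)]]
    if (is.null(quants)) abort(sprintf("no quantitation table for K = %d.", K))
    sel <- greedy_forward_select(train, quants, seq_len(K),
                                 n_select = min(n_max, K),
                                 controlled = controlled, baseline_spec = spec0)
    selections[[as.character(K)]] <- sel
    for (n_sel in n_grid[n_grid <= length(sel$selected_ids)]) {
      ids <- sel$selected_ids[seq_len(n_sel)]
      spec <- design_spec(train, ml_feature_ids = ids,
                          covariates = if (controlled) covariate_names() else character(0))
      fit <- fit_logistic(encode_design(train, spec, quants))
      scores <- predict(fit, encode_design(tune, spec, quants))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        K = K, n_selected = n_sel,
        tune_auroc = auroc(scores, tune$lnm))
    }
  }
  grid <- dplyr::bind_rows(rows)
  ord <- order(-grid$tune_auroc, grid$K, grid$n_selected)
  best_row <- grid[ord[1L], ]
  best_K <- as.character(best_row$K)
  structure(dplyr::as_tibble(grid),
            best = list(K = best_row$K, n_selected = best_row$n_selected,
                        tune_auroc = best_row$tune_auroc,
                        selected_ids = selections[[best_K]]$selected_ids[
                          seq_len(best_row$n_selected)]),
            selections = selections,
            class = c("histofeat_grid", class(grid)))
}
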