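# End-to-end orchestration: simulate (or read) -> cluster -> quantitate ->
# select -> evaluate -> survival -> report. All randomness flows through
# the seeds in the pipeline configuration, so a fixed configuration yields
# byte-identical reports across runs.

#' Run the full feature-discovery pipeline
#'
#' Fits the k-means cluster model on patches sampled from the training
#' split, quantitates every case, selects clusters by greedy forward
#' selection on the training split (optionally choosing K and the feature
#' count on the tune split), evaluates the selected features on the
#' validation split (likelihood-ratio test, odds ratios, predictive AUROC
#' gain, operating point, univariable statistics, batch-confound check when
#' batches are present), runs the survival risk stratification, and writes
#' all reports to `out_dir`.
#'
#' @param cohort A `synth_cohort`, or a list with `cases` and `embeddings`
#'   tibbles (e.g. from [read_cohort()]).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all fitted objects and report paths.
#' @export
run_pipeline <- function(cohort, out_dir, config = pipeline_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cases <- cohort$cases
  embeddings <- cohort$embeddings
  train <- cases[cases$split == "train", , drop = FALSE]
  tune <- cases[cases$split == "tune", , drop = FALSE]
  validation <- cases[cases$split == "validation", , drop = FALSE]
  if (nrow(train) == 0L || nrow(validation) == 0L) {
    abort("pipeline needs nonempty train and validation splits.")
  }

  train_emb <- embeddings[embeddings$case_id %in% train$case_id, , drop = FALSE]
  sampled <- sample_patches(train_emb, n_per_case = config$patches_per_case,
                            seed = config$clustering_seed)

  if (isTRUE(config$run_grid)) {
    if (nrow(tune) == 0L) abort("grid search needs a tune split.")
    quants_by_K <- list()
    models <- list()
    for (K in config$K_grid) {
      m <- fit_clusters(sampled, K = K, seed = config$clustering_seed,
                        n_restarts = config$n_restarts)
      models[[as.character(K)]] <- m
      quants_by_K[[as.character(K)]] <- quantitate_cases(m, embeddings)
    }
    grid <- hyperparameter_grid(cases, quants_by_K, K_grid = config$K_grid,
                                n_grid = seq_len(config$n_select_max),
                                controlled = config$controlled)
    best <- attr(grid, "best")
    K_used <- best$K
    model <- models[[as.character(K_used)]]
    quants <- quants_by_K[[as.character(K_used)]]
    selected_ids <- best$selected_ids
    selection <- attr(grid, "selections")[[as.character(K_used)]]
  } else {
    grid <- NULL
    K_used <- config$K
    model <- fit_clusters(sampled, K = K_used, seed = config$clustering_seed,
                          n_restarts = config$n_restarts)
    quants <- quantitate_cases(model, embeddings)
    selection <- greedy_forward_select(train, quants,
                                       candidate_ids = seq_len(K_used),
                                       n_select = config$n_select,
                                       controlled = config$controlled)
    selected_ids <- selection$selected_ids
  }

  # --- evaluation on the validation split ---
  lrt <- likelihood_ratio_test(validation, quants, selected_ids)
  spec_val <- design_spec(validation, ml_feature_ids = selected_ids)
  fit_val <- fit_logistic(encode_design(validation, spec_val, quants))
  ors <- odds_ratio_table(fit_val, spec_val)
  pred <- predictive_evaluation(train, validation, quants, selected_ids,
                                n_boot = config$n_boot,
                                seed = config$bootstrap_seed)
  op <- operating_point(pred$scores$combined, pred$scores$lnm)
  uni <- dplyr::bind_rows(lapply(selected_ids, function(id)
    univariable_feature_stats(validation, quants, id)))
  confound <- NULL
  if (!is.null(validation[["batch"]]) &&
      length(unique(validation$batch)) >= 2L &&
      all(table(validation$batch[validation$lnm == 0L]) > 0L)) {
    confound <- batch_confound_check(validation, pred$scores$combined,
                                     alpha = config$confound_alpha)
  }

  # --- survival risk stratification ---
  surv <- NULL
  if (!is.null(cases[["survival_time"]]) && !anyNA(cases$survival_time)) {
    dev <- cases[cases$split %in% c("train", "tune"), , drop = FALSE]
    rmodel <- risk_scores(dev, quants, selected_ids,
                          target = config$risk_target)
    win <- config$threshold_year_window %||%
      c(max(dev$accrual_year) - 4L, max(dev$accrual_year))
    thr <- median_threshold(dev, predict(rmodel, dev, quants), win)
    val_scores <- predict(rmodel, validation, quants)
    surv <- tryCatch(
      stratified_km_report(validation, val_scores, thr,
                           horizon_years = config$horizon_years),
      error = function(e) {
        warn(paste("risk stratification skipped:", conditionMessage(e)))
        NULL
      })
  }

  result <- list(model = model, quants = quants, selection = selection,
                 grid = grid, selected_ids = selected_ids, lrt = lrt,
                 odds_ratios = ors, predictive = pred, operating_point = op,
                 univariable = uni, confound = confound, survival = surv,
                 config = config, K = K_used)
  write_pipeline_report(result, out_dir)
  invisible(result)
}

fmt_num <- function(x, digits = 6) formatC(x, digits = digits, format = "g")

write_pipeline_report <- function(res, out_dir) {
  readr::write_csv(res$odds_ratios, file.path(out_dir, "odds_ratios.csv"),
                   progress = FALSE)
  readr::write_csv(res$univariable, file.path(out_dir, "univariable.csv"),
                   progress = FALSE)
  readr::write_csv(tidy(res$selection), file.path(out_dir, "selection.csv"),
                   progress = FALSE)
  if (!is.null(res$grid)) {
    readr::write_csv(tibble::as_tibble(res$grid), file.path(out_dir, "grid.csv"),
                     progress = FALSE)
  }
  if (!is.null(res$survival)) {
    km_rows <- list()
    for (st in names(res$survival)) {
      for (g in names(res$survival[[st]]$km)) {
        steps <- res$survival[[st]]$km[[g]]$steps
        steps$stage <- st
        steps$group <- g
        km_rows[[paste(st, g)]] <- steps
      }
    }
    readr::write_csv(dplyr::bind_rows(km_rows), file.path(out_dir, "km_curves.csv"),
                     progress = FALSE)
  }

  p <- res$predictive
  lines <- c(
    "Machine-learned histologic features: pipeline report",
    sprintf("K = %d clusters; selected ids: %s (%s selection)",
            res$K, paste(res$selected_ids, collapse = ", "),
            if (res$selection$controlled) "controlled" else "uncontrolled"),
    "",
    "[1] Likelihood-ratio test (validation fit): null = clinicopathologic variables,",
    sprintf("    alternative adds %d machine-learned features:", res$lrt$df),
    sprintf("    chi-square = %s, df = %d, p = %s",
            fmt_num(res$lrt$statistic), res$lrt$df, fmt_num(res$lrt$p_value)),
    "",
    "[2] Multivariable odds ratios: see odds_ratios.csv",
    "",
    "[3] AUROC for LNM prediction (trained on train split, evaluated on validation):",
    sprintf("    Clinical       %s [%s, %s]", fmt_num(p$auroc_clinical),
            fmt_num(p$ci_clinical[1]), fmt_num(p$ci_clinical[2])),
    sprintf("    Clinical + ML  %s [%s, %s]", fmt_num(p$auroc_combined),
            fmt_num(p$ci_combined[1]), fmt_num(p$ci_combined[2])),
    sprintf("    ML only        %s [%s, %s]", fmt_num(p$auroc_ml_only),
            fmt_num(p$ci_ml_only[1]), fmt_num(p$ci_ml_only[2])),
    sprintf("    Delta          %s [%s, %s]", fmt_num(p$delta),
            fmt_num(p$ci_delta[1]), fmt_num(p$ci_delta[2])),
    "",
    sprintf("Operating point (max harmonic mean Se/Sp): threshold %s, Se %s, Sp %s, PPV %s, NPV %s",
            fmt_num(res$operating_point$threshold),
            fmt_num(res$operating_point$sensitivity),
            fmt_num(res$operating_point$specificity),
            fmt_num(res$operating_point$ppv), fmt_num(res$operating_point$npv)))
  if (!is.null(res$confound)) {
    lines <- c(lines, "",
               sprintf("Batch confound check (label-negative cases): p = %s — %s",
                       fmt_num(res$confound$p_value),
                       if (res$confound$flag) "FLAGGED" else "no flag"))
  }
  if (!is.null(res$survival)) {
    lines <- c(lines, "", "Risk stratification (validation split):")
    for (st in names(res$survival)) {
      s <- res$survival[[st]]
      lines <- c(lines, sprintf("  %s: log-rank p = %s", st, fmt_num(s$logrank_p)))
      for (i in seq_len(nrow(s$five_year))) {
        lines <- c(lines, sprintf("    %4s risk (n = %d): %g-year survival %s [%s, %s]",
                                  s$five_year$group[i], s$five_year$n[i],
                                  s$horizon_years, fmt_num(s$five_year$survival[i]),
                                  fmt_num(s$five_year$ci_low[i]),
                                  fmt_num(s$five_year$ci_high[i])))
      }
    }
  }
  writeLines(lines, file.path(out_dir, "report.txt"))

  cfg <- res$config
  manifest <- list(
    config_hash = rlang::hash(unclass(cfg)),
    K = res$K, selected_ids = res$selected_ids,
    seeds = list(clustering = cfg$clustering_seed,
                 bootstrap = cfg$bootstrap_seed,
                 generator = cfg$generator_seed),
    n_boot = cfg$n_boot, controlled = cfg$controlled)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
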