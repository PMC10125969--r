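# File formats: delimited covariate tables, embedding containers (single
# CSV or directory-of-CSVs), quantitation tables, cluster models, selection
# results and the pipeline configuration. The case id is the join key
# everywhere; split assignments live in the covariate table.

required_covariate_cols <- function() {
  c("case_id", covariate_names(), "lnm", "split")
}

optional_covariate_cols <- function() {
  c("survival_time", "event", "accrual_year", "batch")
}

# Normalize a categorical value case-insensitively against its level set.
normalize_level <- function(values, levels, column) {
  idx <- match(tolower(trimws(values)), tolower(levels))
  bad <- which(is.na(idx) & !is.na(values))
  if (length(bad) > 0L) {
    abort(sprintf("invalid %s value '%s' at row %d.",
                  column, values[bad[1L]], bad[1L]))
  }
  levels[idx]
}

#' Read a case-level covariate table
#'
#' Delimited text (comma or tab, sniffed from the header line) with one row
#' per case. Required columns: `case_id`, the six baseline covariates,
#' `lnm`, `split`; optional: `survival_time`, `event`, `accrual_year`,
#' `batch`. Categorical values are normalized case-insensitively to their
#' canonical spelling; unknown columns are preserved; row order is retained.
#'
#' @param path File path.
#' @return Tibble of validated case records.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("covariate table does not exist: %s", path))
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing <- setdiff(required_covariate_cols(), names(tbl))
  if (length(missing) > 0L) {
    abort(sprintf("covariate table missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  tbl$case_id <- as.character(tbl$case_id)
  dup <- tbl$case_id[duplicated(tbl$case_id)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicated case_id: %s", paste(unique(dup), collapse = ", ")))
  }
  lv <- covariate_levels()
  for (nm in names(lv)) {
    tbl[[nm]] <- normalize_level(as.character(tbl[[nm]]), lv[[nm]], nm)
  }
  tbl$split <- normalize_level(as.character(tbl$split),
                               c("train", "tune", "validation"), "split")
  tbl$lnm <- as_binary01(tbl$lnm, "lnm")
  if (!is.null(tbl[["event"]])) {
    has_event <- !is.na(tbl[["event"]])
    st <- tbl[["survival_time"]]
    if (is.null(st) || any(has_event & (is.na(st) | st < 0))) {
      abort("records with an event indicator need a nonnegative survival_time.")
    }
  }
  tbl
}

#' Write a case-level covariate table
#'
#' @param records Tibble of case records.
#' @param path Output file (CSV).
#' @return `path`, invisibly.
#' @export
write_covariates <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read patch embeddings
#'
#' Two dialects: a single delimited file with columns `case_id`, `patch_id`,
#' `e1..ed` (one row per patch), or a directory of per-case files named
#' `<case_id>.csv` each holding `patch_id`, `e1..ed`. A uniform embedding
#' dimension is enforced across cases and empty bags are rejected.
#'
#' @param path File or directory.
#' @return Tibble `case_id`, `patch_id`, `e1..ed`.
#' @export
read_embeddings <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0L) abort(sprintf("no per-case csv files in %s.", path))
    parts <- lapply(files, function(f) {
      tbl <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
      dplyr::bind_cols(tibble::tibble(case_id = sub("\\.csv$", "", basename(f))), tbl)
    })
    dims <- vapply(parts, function(p) length(embedding_cols(p)), integer(1))
    if (length(unique(dims)) > 1L) {
      abort(sprintf("embedding dimension mismatch across cases: %s.",
                    paste(unique(dims), collapse = " vs ")))
    }
    emb <- dplyr::bind_rows(parts)
  } else {
    emb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("case_id", "patch_id") %in% names(emb))) {
      abort("embedding file must have case_id and patch_id columns.")
    }
    emb$case_id <- as.character(emb$case_id)
  }
  ecols <- embedding_cols(emb)
  if (anyNA(emb[, ecols])) abort("missing values in embedding columns.")
  dup <- duplicated(paste(emb$case_id, emb$patch_id))
  if (any(dup)) abort("duplicated (case_id, patch_id) pairs.")
  emb
}

#' Write patch embeddings
#'
#' @param embeddings Tibble `case_id`, `patch_id`, `e1..ed`.
#' @param path Output file (single-file dialect) or directory
#'   (directory-of-files dialect).
#' @param dialect `"single"` or `"dir"`.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path, dialect = c("single", "dir")) {
  dialect <- match.arg(dialect)
  if (dialect == "single") {
    readr::write_csv(embeddings, path, progress = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (cid in unique(embeddings$case_id)) {
      part <- embeddings[embeddings$case_id == cid,
                         setdiff(names(embeddings), "case_id"), drop = FALSE]
      readr::write_csv(part, file.path(path, paste0(cid, ".csv")), progress = FALSE)
    }
  }
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Emits `covariates.csv`, `embeddings.csv` and the truth sidecar
#' `truth.csv` (case id, true component proportions, linear score, batch)
#' into `out_dir`. Round-trips losslessly (up to float representation)
#' through [read_cohort()].
#'
#' @param cohort A `synth_cohort`.
#' @param out_dir Output directory (created if absent).
#' @param overwrite Allow replacing existing files?
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, overwrite = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("covariates.csv", "embeddings.csv", "truth.csv"))
  if (!overwrite && any(file.exists(paths))) {
    abort(sprintf("output files already exist in %s (set overwrite = TRUE).", out_dir))
  }
  write_covariates(cohort$cases, paths[1L])
  readr::write_csv(cohort$embeddings, paths[2L], progress = FALSE)
  readr::write_csv(cohort$truth$proportions, paths[3L], progress = FALSE)
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `covariates.csv`, `embeddings.csv` and
#'   (optionally) `truth.csv`.
#' @param strict Error (default) or warn-and-drop when cases are present in
#'   one file but not the other.
#' @return List `cases`, `embeddings`, `truth` (tibble or NULL).
#' @export
read_cohort <- function(dir, strict = TRUE) {
  cases <- read_covariates(file.path(dir, "covariates.csv"))
  embeddings <- read_embeddings(file.path(dir, "embeddings.csv"))
  only_cov <- setdiff(cases$case_id, embeddings$case_id)
  only_emb <- setdiff(embeddings$case_id, cases$case_id)
  if (length(only_cov) > 0L || length(only_emb) > 0L) {
    msg <- sprintf("%d case(s) missing embeddings, %d missing covariates.",
                   length(only_cov), length(only_emb))
    if (strict) abort(paste(msg, "Use strict = FALSE to drop them."))
    warn(paste(msg, "Dropping them."))
    keep <- intersect(cases$case_id, unique(embeddings$case_id))
    cases <- cases[cases$case_id %in% keep, , drop = FALSE]
    embeddings <- embeddings[embeddings$case_id %in% keep, , drop = FALSE]
  }
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  list(cases = cases, embeddings = embeddings, truth = truth)
}

#' Persist a cluster model
#'
#' Centroids as CSV plus a YAML metadata record (K, dimension, seed,
#' inertia).
#'
#' @param model A `cluster_model`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cluster_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cent <- tibble::as_tibble(model$centroids, .name_repair = "minimal")
  names(cent) <- paste0("e", seq_len(model$dim))
  readr::write_csv(dplyr::bind_cols(tibble::tibble(cluster = seq_len(model$K)), cent),
                   file.path(dir, "centroids.csv"), progress = FALSE)
  yaml::write_yaml(list(K = model$K, dim = model$dim, fit_seed = model$fit_seed,
                        inertia = model$inertia),
                   file.path(dir, "model.yaml"))
  invisible(dir)
}

#' Read a persisted cluster model
#'
#' @param dir Directory written by [write_cluster_model()].
#' @return A `cluster_model`.
#' @export
read_cluster_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  cent <- readr::read_csv(file.path(dir, "centroids.csv"),
                          show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(cent[, paste0("e", seq_len(meta$dim)), drop = FALSE])
  dimnames(m) <- NULL
  structure(list(centroids = m, K = meta$K, dim = meta$dim,
                 fit_seed = meta$fit_seed, inertia = meta$inertia,
                 inertia_trace = NULL),
            class = "cluster_model")
}

#' Write / read a quantitation table
#'
#' @param quants Tibble `case_id`, `cl_1..cl_K`.
#' @param path CSV path.
#' @return `path` / the tibble.
#' @export
write_quantitations <- function(quants, path) {
  readr::write_csv(quants, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_quantitations
#' @export
read_quantitations <- function(path) {
  q <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  q$case_id <- as.character(q$case_id)
  bad <- abs(rowSums(q[, quant_col(seq_len(quant_K(q))), drop = FALSE]) - 1) > 1e-6
  if (any(bad)) abort("quantitation rows must sum to 1.")
  q
}

#' Pipeline configuration
#'
#' Defaults reproduce the reference configuration: candidate grid
#' K in (10, 25, 50, 100, 200), 1-10 selected features with 5 the default,
#' 64 patches sampled per case for cluster fitting, 1000 bootstrap
#' resamples, controlled selection.
#'
#' @param ... Overrides of the default fields.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    K_grid = c(10L, 25L, 50L, 100L, 200L),
    n_select_max = 10L,
    n_select = 5L,
    patches_per_case = 64L,
    n_boot = 1000L,
    controlled = TRUE,
    run_grid = FALSE,
    K = 200L,
    clustering_seed = 1L,
    bootstrap_seed = 1L,
    generator_seed = 1L,
    n_restarts = 10L,
    horizon_years = 5,
    threshold_year_window = NULL,
    risk_target = "lnm",
    confound_alpha = 0.01,
    generator = list()
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown pipeline_config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path) %||% list()
  do.call(pipeline_config, vals)
}
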