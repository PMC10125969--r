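# Shared fixtures and independent oracles. Oracles are deliberately naive
# (brute-force enumeration / closed forms) and never call the code paths
# they check.

# --- fixture builders -------------------------------------------------------

# A small tibble of case records; covariates are drawn with a fixed
# internal seed so repeated calls agree but columns are not collinear
# (cyclic level assignment would alias the binary covariates).
make_records <- function(n, lnm = rep_len(c(0L, 1L), n), split = "train",
                         seed = 42) {
  lv <- histofeat:::covariate_levels()
  draw <- withr::with_seed(seed, {
    lapply(lv, function(levels) sample(levels, n, replace = TRUE))
  })
  tibble::tibble(
    case_id = sprintf("c%03d", seq_len(n)),
    age_group = draw$age_group,
    sex = draw$sex,
    grade = draw$grade,
    t_category = draw$t_category,
    lymphatic_invasion = draw$lymphatic_invasion,
    venous_invasion = draw$venous_invasion,
    lnm = rep_len(lnm, n),
    split = rep_len(split, n),
    survival_time = NA_real_, event = NA_integer_,
    accrual_year = NA_integer_, batch = NA_character_)
}

# A quantitation table with given fraction matrix (rows sum to 1).
make_quants <- function(case_ids, frac) {
  out <- tibble::as_tibble(as.data.frame(frac), .name_repair = "minimal")
  names(out) <- paste0("cl_", seq_len(ncol(frac)))
  dplyr::bind_cols(tibble::tibble(case_id = case_ids), out)
}

# Random simplex rows (independent of the package's Dirichlet helper).
random_simplex <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}

# A tiny embedding tibble from a matrix.
make_embeddings <- function(case_id, x, patch_id = NULL) {
  out <- tibble::as_tibble(as.data.frame(x), .name_repair = "minimal")
  names(out) <- paste0("e", seq_len(ncol(x)))
  dplyr::bind_cols(
    tibble::tibble(case_id = case_id,
                   patch_id = patch_id %||% paste0("p", seq_along(case_id))),
    out)
}

`%||%` <- rlang::`%||%`

# --- independent oracles ----------------------------------------------------

# O(n^2) pairwise AUROC with half-credit ties.
auroc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Brute-force greedy forward selection over the same recurrence, built on
# stats::glm with formulas rather than the package's fitting path.
brute_greedy <- function(records, quants, candidate_ids, n_select,
                         controlled = TRUE) {
  y <- records$lnm
  base_df <- data.frame(
    age_group = factor(records$age_group, histofeat:::covariate_levels()$age_group),
    sex = factor(records$sex, histofeat:::covariate_levels()$sex),
    grade = factor(records$grade, histofeat:::covariate_levels()$grade),
    t_category = factor(records$t_category, histofeat:::covariate_levels()$t_category),
    lymphatic_invasion = factor(records$lymphatic_invasion,
                                histofeat:::covariate_levels()$lymphatic_invasion),
    venous_invasion = factor(records$venous_invasion,
                             histofeat:::covariate_levels()$venous_invasion))
  base_df <- droplevels(base_df)
  qcols <- function(ids) {
    m <- as.data.frame(quants[match(records$case_id, quants$case_id),
                              paste0("cl_", ids), drop = FALSE])
    names(m) <- paste0("f", ids)
    m
  }
  selected <- integer(0)
  trace <- numeric(0)
  remaining <- candidate_ids
  for (step in seq_len(n_select)) {
    best <- c(auc = -Inf, id = NA)
    for (id in sort(remaining)) {
      df <- if (controlled) cbind(base_df, qcols(c(selected, id)))
            else qcols(c(selected, id))
      df$y <- y
      fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = binomial()))
      auc <- auroc_pairwise(fitted(fit), y)
      if (auc > best["auc"] + 1e-12) best <- c(auc = auc, id = id)
    }
    selected <- c(selected, best["id"])
    trace <- c(trace, best["auc"])
    remaining <- setdiff(remaining, best["id"])
  }
  list(selected_ids = unname(selected), step_aurocs = unname(trace))
}

# Exhaustive exemplar retrieval under the one-patch-per-case constraint.
brute_exemplars <- function(centroid, embeddings, n) {
  x <- as.matrix(embeddings[, grep("^e[0-9]+$", names(embeddings))])
  d <- sqrt(rowSums(sweep(x, 2, centroid)^2))
  df <- data.frame(case_id = embeddings$case_id,
                   patch_id = embeddings$patch_id, distance = d,
                   stringsAsFactors = FALSE)
  df <- df[order(df$distance, df$case_id, df$patch_id), ]
  picked <- df[!duplicated(df$case_id), ][seq_len(n), ]
  rownames(picked) <- NULL
  picked
}

# Exhaustive operating-point search over candidate thresholds.
brute_operating_point <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(min(s) - 1, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2)
  best <- NULL
  for (t in cand) {
    pred <- scores >= t
    se <- sum(pred & labels == 1) / sum(labels == 1)
    sp <- sum(!pred & labels == 0) / sum(labels == 0)
    hm <- if (se + sp == 0) 0 else 2 * se * sp / (se + sp)
    if (is.null(best) || hm > best$hm + 1e-12) best <- list(t = t, hm = hm)
  }
  best
}

# Small planted-signal quantitation scenario used by selection tests:
# cluster `signal_id`'s fraction is shifted by the label, the rest is noise.
planted_quants <- function(records, K, signal_id, shift = 0.25) {
  n <- nrow(records)
  frac <- random_simplex(n, K)
  bump <- shift * records$lnm
  frac[, signal_id] <- frac[, signal_id] + bump
  frac <- frac / rowSums(frac)
  make_quants(records$case_id, frac)
}
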