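# Patch sampling, k-means fitting, cluster assignment and case-level
# quantitation. Quantitation always uses ALL patches of a case; the random
# per-case sample is only used to fit the cluster model.

#' Sample patches per case for cluster fitting
#'
#' Samples up to `n_per_case` embedding vectors uniformly without replacement
#' from each case's bag (all vectors when the bag is smaller, with no
#' duplication). Output order is case order, then within-case sample order.
#'
#' @param embeddings Tibble with `case_id`, `patch_id` and embedding columns
#'   `e1..ed` (one row per patch).
#' @param n_per_case Patches to draw per case (default 64).
#' @param seed Integer seed; sampling is deterministic given it.
#' @return Tibble of sampled rows, same columns as `embeddings`.
#' @export
sample_patches <- function(embeddings, n_per_case = 64L, seed = 1L) {
  n_per_case <- assert_count(n_per_case, "n_per_case")
  if (nrow(embeddings) == 0L) abort("`embeddings` is empty.")
  case_ids <- unique(embeddings$case_id)
  withr::with_seed(as.integer(seed), {
    idx_by_case <- split(seq_len(nrow(embeddings)), factor(embeddings$case_id, levels = case_ids))
    take <- lapply(idx_by_case, function(idx) {
      if (length(idx) <= n_per_case) idx
      else idx[sample.int(length(idx), n_per_case)]
    })
    embeddings[unlist(take, use.names = FALSE), , drop = FALSE]
  })
}

embedding_cols <- function(embeddings) {
  cols <- grep("^e[0-9]+$", names(embeddings), value = TRUE)
  if (length(cols) == 0L) abort("no embedding columns (e1..ed) found.")
  cols[order(as.integer(sub("^e", "", cols)))]
}

as_embedding_matrix <- function(embeddings) {
  as.matrix(embeddings[, embedding_cols(embeddings), drop = FALSE])
}

# Squared Euclidean distances between rows of x and rows of centers.
sqdist_to_centers <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

# Greedy k-means++ seeding (Arthur & Vassilvitskii, with the multi-candidate
# refinement scikit-learn uses): at each step, 2 + floor(log(k)) candidates
# are drawn with probability proportional to squared distance from the
# nearest chosen center, and the one minimizing the resulting potential wins.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  xs <- rowSums(x^2)
  pt_d2 <- function(i) pmax(xs + xs[i] - 2 * drop(x %*% x[i, ]), 0)
  n_cand <- 2L + as.integer(floor(log(k)))
  centers <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1L)
  centers[1L, ] <- x[first, ]
  d2 <- pt_d2(first)
  for (j in seq_len(k - 1L)) {
    tot <- sum(d2)
    cand <- if (tot <= 0) sample.int(n, n_cand, replace = TRUE) else
      sample.int(n, n_cand, replace = TRUE, prob = d2 / tot)
    best_pot <- Inf
    best_d2 <- NULL
    best_i <- cand[1L]
    for (i in cand) {
      di <- pmin(d2, pt_d2(i))
      pot <- sum(di)
      if (pot < best_pot) {
        best_pot <- pot
        best_d2 <- di
        best_i <- i
      }
    }
    centers[j + 1L, ] <- x[best_i, ]
    d2 <- best_d2
  }
  centers
}

lloyd <- function(x, centers, max_iter, tol) {
  k <- nrow(centers)
  inertia_trace <- numeric(0)
  prev_inertia <- Inf
  assign <- integer(nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- sqdist_to_centers(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(nrow(x)), assign)])
    inertia_trace <- c(inertia_trace, inertia)
    for (j in seq_len(k)) {
      mem <- assign == j
      # empty cluster: re-seed at the point farthest from its center
      if (!any(mem)) {
        far <- which.max(d2[cbind(seq_len(nrow(x)), assign)])
        centers[j, ] <- x[far, ]
      } else {
        centers[j, ] <- colMeans(x[mem, , drop = FALSE])
      }
    }
    if (prev_inertia - inertia <= tol * abs(prev_inertia)) break
    prev_inertia <- inertia
  }
  # final inertia at the converged centers
  d2 <- sqdist_to_centers(x, centers)
  assign <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(x)), assign)])
  list(centers = centers, assign = assign,
       inertia = inertia, inertia_trace = inertia_trace)
}

#' Fit a k-means cluster model on sampled patch embeddings
#'
#' Lloyd's algorithm with k-means++ initialization, multiple restarts, and
#' the best (lowest-inertia) solution retained. Deterministic given `seed`.
#'
#' @param samples Tibble of sampled patch rows (from [sample_patches()]) or a
#'   numeric matrix of embeddings.
#' @param K Number of clusters (the candidate feature count).
#' @param seed Integer seed for initialization.
#' @param n_restarts Independent k-means++ restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param tol Relative inertia-improvement tolerance for convergence.
#' @return A `cluster_model` with `centroids` (K x d), `K`, `fit_seed`,
#'   `inertia` and the per-iteration `inertia_trace` of the winning restart.
#' @export
fit_clusters <- function(samples, K, seed = 1L, n_restarts = 10L,
                         max_iter = 300L, tol = 1e-4) {
  K <- assert_count(K, "K")
  x <- if (is.matrix(samples)) samples else as_embedding_matrix(samples)
  storage.mode(x) <- "double"
  if (nrow(x) < K) {
    abort(sprintf("need at least K = %d samples, got %d.", K, nrow(x)))
  }
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_restarts)) {
      fit <- lloyd(x, kmeanspp_init(x, K), max_iter, tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(list(centroids = best$centers, K = K, dim = ncol(x),
                 fit_seed = as.integer(seed), inertia = best$inertia,
                 inertia_trace = best$inertia_trace),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K = %d, dim = %d, inertia = %.4g (seed %d)\n",
              x$K, x$dim, x$inertia, x$fit_seed))
  invisible(x)
}

#' Assign patches to their nearest cluster
#'
#' Each patch is assigned to the nearest centroid by Euclidean distance;
#' exact ties go to the lowest cluster id.
#'
#' @param model A `cluster_model`.
#' @param embeddings Tibble of patch rows (any number of cases).
#' @return Tibble `case_id`, `patch_id`, `cluster` (1..K).
#' @export
assign_clusters <- function(model, embeddings) {
  x <- as_embedding_matrix(embeddings)
  if (ncol(x) != model$dim) {
    abort(sprintf("embedding dimension %d does not match model dimension %d.",
                  ncol(x), model$dim))
  }
  d2 <- sqdist_to_centers(x, model$centroids)
  tibble::tibble(case_id = embeddings$case_id,
                 patch_id = embeddings$patch_id %||%
                   paste0("p", seq_len(nrow(embeddings))),
                 cluster = max.col(-d2, ties.method = "first"))
}

#' Cluster quantitation vector for one case
#'
#' The fraction of a case's patches assigned to each of the K clusters — a
#' simplex vector (nonnegative, summing to 1).
#'
#' @param assignments Integer vector of cluster ids (1..K), one per patch.
#' @param K Number of clusters.
#' @return Numeric vector of length K summing to 1.
#' @export
quantitate <- function(assignments, K) {
  K <- assert_count(K, "K")
  if (length(assignments) == 0L) {
    abort("a case with zero patches has no quantitation vector.")
  }
  if (any(assignments < 1L | assignments > K)) {
    abort("cluster ids must lie in 1..K.")
  }
  tabulate(assignments, nbins = K) / length(assignments)
}

#' Case-level quantitation table
#'
#' Assigns all patches of every case to clusters and computes each case's
#' quantitation vector. All patches of a case are used (not only the ones
#' sampled for model fitting).
#'
#' @param model A `cluster_model`.
#' @param embeddings Tibble of patch rows.
#' @return Tibble `case_id`, `cl_1` .. `cl_K`; each row sums to 1.
#' @export
quantitate_cases <- function(model, embeddings) {
  asg <- assign_clusters(model, embeddings)
  case_ids <- unique(asg$case_id)
  counts <- table(factor(asg$case_id, levels = case_ids),
                  factor(asg$cluster, levels = seq_len(model$K)))
  frac <- matrix(as.numeric(counts / rowSums(counts)),
                 nrow = length(case_ids), ncol = model$K)
  out <- tibble::as_tibble(frac, .name_repair = "minimal")
  names(out) <- quant_col(seq_len(model$K))
  dplyr::bind_cols(tibble::tibble(case_id = case_ids), out)
}

#' Exemplar patches for a cluster
#'
#' The `n` patches nearest a cluster's centroid subject to at most one patch
#' per case, sorted ascending by distance, distance ties broken by
#' `(case_id, patch_id)` lexicographically. Used to show what a
#' machine-learned feature looks like across distinct cases.
#'
#' @param model A `cluster_model`.
#' @param embeddings Tibble of patch rows.
#' @param cluster_id Cluster to characterise (1..K).
#' @param n Number of exemplars.
#' @return Tibble `case_id`, `patch_id`, `distance` with `n` rows.
#' @export
exemplar_patches <- function(model, embeddings, cluster_id, n = 5L) {
  n <- assert_count(n, "n")
  cluster_id <- assert_count(cluster_id, "cluster_id")
  if (cluster_id > model$K) abort("`cluster_id` exceeds K.")
  x <- as_embedding_matrix(embeddings)
  if (ncol(x) != model$dim) abort("embedding dimension mismatch.")
  dist <- sqrt(rowSums(sweep(x, 2L, model$centroids[cluster_id, ])^2))
  cand <- tibble::tibble(case_id = embeddings$case_id,
                         patch_id = embeddings$patch_id %||%
                           paste0("p", seq_len(nrow(embeddings))),
                         distance = dist)
  cand <- cand[order(cand$distance, cand$case_id, cand$patch_id), ]
  cand <- cand[!duplicated(cand$case_id), ]
  if (nrow(cand) < n) {
    abort(sprintf("only %d distinct cases have patches; cannot return %d exemplars.",
                  nrow(cand), n))
  }
  cand[seq_len(n), ]
}
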