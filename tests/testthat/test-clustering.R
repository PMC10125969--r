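# Patch sampling, k-means fitting, assignment, quantitation and exemplar
# retrieval, each against closed forms or brute-force oracles.

test_that("sample_patches takes min(n, bag size) without replacement, deterministically", {
  set.seed(1)
  emb <- dplyr::bind_rows(
    make_embeddings(rep("big", 100), matrix(rnorm(300), 100, 3),
                    patch_id = paste0("b", 1:100)),
    make_embeddings(rep("small", 10), matrix(rnorm(30), 10, 3),
                    patch_id = paste0("s", 1:10)))
  s <- sample_patches(emb, n_per_case = 64, seed = 5)
  expect_equal(sum(s$case_id == "big"), 64L)
  expect_equal(sum(s$case_id == "small"), 10L)
  expect_false(anyDuplicated(s$patch_id) > 0)
  # case order then within-case order
  expect_equal(unique(s$case_id), c("big", "small"))
  expect_identical(s, sample_patches(emb, n_per_case = 64, seed = 5))
  expect_error(sample_patches(emb, n_per_case = 0), "n_per_case")
})

test_that("K = 1 k-means returns the sample mean; inertia trace is non-increasing", {
  set.seed(2)
  x <- matrix(rnorm(600), 200, 3)
  m <- fit_clusters(x, K = 1, seed = 1, n_restarts = 1)
  expect_equal(drop(m$centroids), colMeans(x), tolerance = 1e-10)
  m2 <- fit_clusters(x, K = 5, seed = 1, n_restarts = 3)
  expect_true(all(diff(m2$inertia_trace) <= 1e-8))
  expect_error(fit_clusters(x[1:3, ], K = 5), "at least K")
})

test_that("two separated blobs are recovered near their per-blob sample means", {
  set.seed(3)
  a <- matrix(rnorm(200 * 2, mean = 0, sd = 1), 200, 2)
  b <- matrix(rnorm(200 * 2, mean = 8, sd = 1), 200, 2)
  m <- fit_clusters(rbind(a, b), K = 2, seed = 1, n_restarts = 4)
  truth <- rbind(colMeans(a), colMeans(b))
  # match centroids to blobs by distance
  ord <- if (sum((m$centroids[1, ] - truth[1, ])^2) <
             sum((m$centroids[2, ] - truth[1, ])^2)) 1:2 else 2:1
  tol <- 3 * (1 / sqrt(200))
  expect_lt(max(abs(m$centroids[ord, ] - truth)), tol)
})

test_that("k-means matches stats::kmeans inertia on well-clustered data", {
  # on clearly separated blobs both implementations reach the same global
  # optimum, so the objective values must agree tightly
  set.seed(4)
  centers <- matrix(rnorm(8 * 4, sd = 12), 8, 4)
  x <- centers[rep(1:8, each = 60), ] + matrix(rnorm(480 * 4), 480, 4)
  ours <- fit_clusters(x, K = 8, seed = 2, n_restarts = 10)
  ref <- suppressWarnings(kmeans(x, centers = 8, nstart = 25, iter.max = 100,
                                 algorithm = "Lloyd"))
  expect_lt(abs(ours$inertia - ref$tot.withinss) / ref$tot.withinss, 0.005)
})

test_that("assignment is nearest-centroid with lowest-id tie-breaking", {
  model <- structure(list(centroids = rbind(c(-1, 0), c(5, 5), c(0, 3),
                                            c(1, 0)),
                          K = 4L, dim = 2L, fit_seed = 1L, inertia = 0),
                     class = "cluster_model")
  emb <- make_embeddings(rep("c", 3), rbind(c(0, 3), c(0, 0), c(5, 5)))
  asg <- assign_clusters(model, emb)
  # patch 1 exactly at centroid 3; patch 2 equidistant from 1 and 4 -> 1
  expect_equal(asg$cluster, c(3L, 1L, 2L))
  expect_error(assign_clusters(model, make_embeddings("c", matrix(0, 1, 3))),
               "dimension")
})

test_that("assignment of the centroids themselves is the identity", {
  set.seed(5)
  m <- fit_clusters(matrix(rnorm(400), 100, 4), K = 7, seed = 1, n_restarts = 2)
  asg <- assign_clusters(m, make_embeddings(paste0("c", 1:7), m$centroids))
  expect_equal(asg$cluster, 1:7)
})

test_that("assignment matches the brute-force distance oracle", {
  set.seed(6)
  m <- fit_clusters(matrix(rnorm(300), 75, 4), K = 6, seed = 1, n_restarts = 2)
  x <- matrix(rnorm(30 * 4), 30, 4)
  asg <- assign_clusters(m, make_embeddings(rep("z", 30), x))
  oracle <- apply(x, 1, function(v)
    which.min(colSums((t(m$centroids) - v)^2)))
  expect_equal(asg$cluster, oracle)
})

test_that("quantitation counts fractions on the simplex", {
  expect_equal(quantitate(c(1L, 1L, 2L, 3L), K = 3), c(0.5, 0.25, 0.25))
  v <- quantitate(rep(6L, 9), K = 10)
  expect_equal(v[6], 1)
  expect_equal(sum(v), 1)
  expect_error(quantitate(integer(0), K = 3), "zero patches")
  expect_error(quantitate(c(1L, 4L), K = 3), "1..K")
  # property: random assignments always sum to 1 and are nonnegative
  for (i in 1:20) {
    a <- sample.int(5, sample(1:40, 1), replace = TRUE)
    q <- quantitate(a, K = 5)
    expect_true(all(q >= 0))
    expect_equal(sum(q), 1, tolerance = 1e-12)
  }
})

test_that("quantitate_cases covers every case with a simplex row", {
  co <- generate_cohort(cohort_config(n_cases = 25, embed_dim = 5,
                                      n_components = 4,
                                      patches_per_case_range = c(3L, 12L),
                                      seed = 10))
  m <- fit_clusters(co$embeddings, K = 4, seed = 1, n_restarts = 2)
  q <- quantitate_cases(m, co$embeddings)
  expect_setequal(q$case_id, co$cases$case_id)
  fr <- as.matrix(q[, paste0("cl_", 1:4)])
  expect_equal(rowSums(fr), rep(1, 25), tolerance = 1e-9)
  expect_true(all(fr >= 0))
})

test_that("exemplar retrieval enforces one patch per case and matches enumeration", {
  set.seed(7)
  x <- matrix(rnorm(40 * 3), 40, 3)
  emb <- make_embeddings(rep(sprintf("k%02d", 1:8), each = 5), x,
                         patch_id = sprintf("p%02d", 1:40))
  m <- fit_clusters(x, K = 3, seed = 2, n_restarts = 2)
  ex <- exemplar_patches(m, emb, cluster_id = 2, n = 5)
  oracle <- brute_exemplars(m$centroids[2, ], emb, 5)
  expect_equal(ex$case_id, oracle$case_id)
  expect_equal(ex$patch_id, oracle$patch_id)
  expect_equal(ex$distance, oracle$distance, tolerance = 1e-12)
  expect_false(anyDuplicated(ex$case_id) > 0)
  expect_equal(order(ex$distance), 1:5)

  # n = 1 is the global minimum
  e1 <- exemplar_patches(m, emb, cluster_id = 2, n = 1)
  d_all <- sqrt(colSums((t(x) - m$centroids[2, ])^2))
  expect_equal(e1$distance, min(d_all), tolerance = 1e-12)

  # two nearest patches in one case -> second exemplar from another case
  near <- m$centroids[1, ]
  emb2 <- make_embeddings(c("dup", "dup", "other"),
                          rbind(near + 0.01, near + 0.02, near + 0.5),
                          patch_id = c("a", "b", "c"))
  e2 <- exemplar_patches(m, emb2, cluster_id = 1, n = 2)
  expect_equal(e2$case_id, c("dup", "other"))
  expect_error(exemplar_patches(m, emb2, cluster_id = 1, n = 3),
               "distinct cases")
})

test_that("components map bijectively to centroids on separated synthetic data", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- cohort_config(n_cases = 60, embed_dim = 8, n_components = 6,
                         patches_per_case_range = c(10L, 14L),
                         centroid_scale = 6, seed = 500 + s)
    co <- generate_cohort(cfg)
    m <- fit_clusters(co$embeddings, K = 6, seed = s, n_restarts = 5)
    cc <- co$truth$component_centroids
    map <- apply(outer(rowSums(cc^2), rowSums(m$centroids^2), "+") -
                   2 * tcrossprod(cc, m$centroids), 1, which.min)
    if (length(unique(map)) == 6L) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
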