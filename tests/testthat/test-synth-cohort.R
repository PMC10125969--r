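# Synthetic cohort generator: determinism, prevalence control, planted
# signal recoverability, batch behaviour, config validation.

test_that("identical seed gives identical cohorts; different seeds differ", {
  cfg <- cohort_config(n_cases = 40, embed_dim = 6, n_components = 4,
                       patches_per_case_range = c(5L, 10L), seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cases, b$cases)
  expect_identical(a$embeddings, b$embeddings)
  expect_identical(a$truth$proportions, b$truth$proportions)
  cfg2 <- cohort_config(n_cases = 40, embed_dim = 6, n_components = 4,
                        patches_per_case_range = c(5L, 10L), seed = 8)
  expect_false(identical(generate_cohort(cfg2)$cases$lnm, a$cases$lnm))
})

test_that("null effects and zero intercept give prevalence 1/2 within binomial error", {
  cfg <- cohort_config(n_cases = 2000, embed_dim = 2, n_components = 3,
                       patches_per_case_range = c(1L, 2L),
                       covariate_logodds_effects = numeric(0),
                       baseline_logodds = 0, seed = 11)
  co <- generate_cohort(cfg)
  prev <- mean(co$cases$lnm)
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("prevalence matches the logistic average of simulated linear scores", {
  cfg <- planted_cohort_config(n_cases = 1500, seed = 3)
  co <- generate_cohort(cfg)
  implied <- mean(plogis(co$truth$proportions$linear_score))
  se <- sqrt(implied * (1 - implied) / nrow(co$cases))
  expect_lt(abs(mean(co$cases$lnm) - implied), 3 * se)
})

test_that("a strongly informative component is recovered by refitting on truth", {
  # oracle: logistic fit of the label on the true component proportion must
  # find a positive coefficient whose Wald CI excludes 0
  hits <- 0L
  for (s in 1:20) {
    cfg <- cohort_config(n_cases = 1000, embed_dim = 2, n_components = 5,
                         patches_per_case_range = c(1L, 2L),
                         informative_components = 2L,
                         component_logodds_effects = 8,
                         covariate_logodds_effects = numeric(0),
                         baseline_logodds = -1.6, seed = 100 + s)
    co <- generate_cohort(cfg)
    fit <- suppressWarnings(
      glm(co$cases$lnm ~ co$truth$proportions$comp_2, family = binomial()))
    ci <- suppressMessages(confint.default(fit))[2, ]
    if (coef(fit)[2] > 0 && ci[1] > 0) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("truth proportions are simplex vectors and bags align with cases", {
  cfg <- cohort_config(n_cases = 30, embed_dim = 5, n_components = 6,
                       patches_per_case_range = c(3L, 9L), seed = 2)
  co <- generate_cohort(cfg)
  p <- as.matrix(co$truth$proportions[, paste0("comp_", 1:6)])
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 30), tolerance = 1e-12)
  expect_setequal(unique(co$embeddings$case_id), co$cases$case_id)
  n_patches <- table(co$embeddings$case_id)
  expect_true(all(n_patches >= 3 & n_patches <= 9))
  expect_false(anyDuplicated(co$embeddings$patch_id) > 0)
})

test_that("batch shift moves embedding means; zero shift leaves batches alike", {
  base <- list(n_cases = 300, embed_dim = 8, n_components = 4,
               patches_per_case_range = c(10L, 20L), batch_fraction = 0.5,
               seed = 21)
  shifted <- generate_cohort(do.call(cohort_config,
                                     c(base, batch_shift_magnitude = 3)))
  flat <- generate_cohort(do.call(cohort_config,
                                  c(base, batch_shift_magnitude = 0)))
  mean_norm <- function(co) {
    x <- as.matrix(co$embeddings[, paste0("e", 1:8)])
    b <- co$cases$batch[match(co$embeddings$case_id, co$cases$case_id)]
    tapply(rowSums(x^2), b, mean)
  }
  ns <- mean_norm(shifted)
  nf <- mean_norm(flat)
  expect_gt(abs(ns["b1"] - ns["b0"]), 5)
  expect_lt(abs(nf["b1"] - nf["b0"]), 3)
})

test_that("covariate coupling shifts proportions and rejects negative outputs", {
  coup <- matrix(0, length(histofeat:::indicator_names()), 4,
                 dimnames = list(histofeat:::indicator_names(), NULL))
  coup["lymphatic_invasion_L1+", 1] <- 0.3
  cfg <- cohort_config(n_cases = 400, embed_dim = 3, n_components = 4,
                       patches_per_case_range = c(2L, 4L),
                       dirichlet_concentration = 30,
                       covariate_component_coupling = coup, seed = 5)
  co <- generate_cohort(cfg)
  p1 <- co$truth$proportions$comp_1
  l1 <- co$cases$lymphatic_invasion == "L1+"
  expect_gt(mean(p1[l1]), mean(p1[!l1]) + 0.1)

  coup_bad <- coup
  coup_bad["lymphatic_invasion_L1+", 1] <- -2
  cfg_bad <- cohort_config(n_cases = 50, embed_dim = 3, n_components = 4,
                           patches_per_case_range = c(2L, 4L),
                           covariate_component_coupling = coup_bad, seed = 5)
  expect_error(generate_cohort(cfg_bad), "negative")
})

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(n_cases = 10, patches_per_case_range = c(5L, 2L)),
               "patches_per_case_range")
  expect_error(cohort_config(n_cases = 10, n_components = 3,
                             informative_components = 7L,
                             component_logodds_effects = 1),
               "informative_components")
  expect_error(cohort_config(n_cases = 10, informative_components = 1L,
                             component_logodds_effects = numeric(0)),
               "align")
  expect_error(cohort_config(n_cases = 10, batch_fraction = 1.5),
               "batch_fraction")
})

test_that("null survival signal gives calibrated log-rank rejections over seeds", {
  # with survival_logHR_per_score = 0 a median-score split is independent of
  # survival, so the log-rank test should reject at about the nominal rate
  rej <- 0L
  n_rep <- 120L
  for (s in seq_len(n_rep)) {
    cfg <- cohort_config(n_cases = 120, embed_dim = 2, n_components = 3,
                         patches_per_case_range = c(1L, 2L),
                         survival_logHR_per_score = 0, seed = 9000 + s)
    co <- generate_cohort(cfg)
    grp <- co$truth$proportions$linear_score >=
      median(co$truth$proportions$linear_score)
    lr <- logrank(co$cases$survival_time[grp], co$cases$event[grp],
                  co$cases$survival_time[!grp], co$cases$event[!grp])
    if (lr$p_value < 0.05) rej <- rej + 1L
  }
  band <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
})
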