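# Regression overlays: parameter recovery, the Fine-Gray/Cox reduction,
# risk surfaces, Moran's I, elastic-net explainability, model comparison
# and multiple-testing adjustment.

sim_logistic <- function(n, beta, seed) {
  set.seed(seed)
  x <- rnorm(n)
  age <- rnorm(n, 70, 8)
  y <- rbinom(n, 1, plogis(-0.5 + beta * x + 0.01 * (age - 70)))
  data.frame(y = y, x = x, age = age)
}

test_that("logistic models recover a planted odds ratio of 2", {
  or_hat <- vapply(1:20, function(s) {
    d <- sim_logistic(5000, log(2), s)
    res <- fit_adjusted_model(d, outcome = "y", predictors = "x",
                              covariates = "age", kind = "logistic")
    res$exp_estimate[res$term == "x"]
  }, numeric(1))
  expect_lt(abs(mean(or_hat) - 2), 0.3)
})

test_that("a null covariate has calibrated confidence intervals", {
  cover <- vapply(1:50, function(s) {
    d <- sim_logistic(500, 0, 100 + s)
    res <- fit_adjusted_model(d, outcome = "y", predictors = "x",
                              covariates = "age", kind = "logistic")
    i <- which(res$term == "x")
    res$ci_low[i] < 1 && res$ci_high[i] > 1
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("Fine-Gray reduces exactly to Cox without competing events", {
  co <- generate_cohort(800, seed = 3, waveforms = "none")
  d <- co$outcomes
  d$event_indicator[d$event_indicator == 2] <- 0    # censor the deaths
  fg <- fit_adjusted_model(d, predictors = "severity", covariates = "age",
                           kind = "fine_gray")
  cx <- fit_adjusted_model(d, predictors = "severity", covariates = "age",
                           kind = "cox")
  expect_equal(fg$estimate, cx$estimate, tolerance = 1e-6)
  expect_equal(fg$p, cx$p, tolerance = 1e-6)
})

test_that("Fine-Gray agrees with the cmprsk implementation", {
  co <- generate_cohort(600, seed = 8, waveforms = "none")
  d <- co$outcomes
  ours <- fit_adjusted_model(d, predictors = "severity", covariates = "age",
                             kind = "fine_gray")
  crr <- cmprsk::crr(d$time_to_event, d$event_indicator,
                     cov1 = cbind(severity = d$severity, age = d$age),
                     failcode = 1, cencode = 0)
  expect_equal(ours$estimate, unname(crr$coef), tolerance = 5e-3)
})

test_that("Cox recovers the planted log hazard ratio with < 5% bias", {
  truth <- 0.7
  est <- vapply(1:20, function(s) {
    co <- generate_cohort(5000, synthetic_outcome_spec(log_hr_per_severity = truth),
                          seed = 200 + s, waveforms = "none")
    res <- fit_adjusted_model(co$outcomes, predictors = "severity",
                              covariates = character(0), kind = "cox")
    res$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - truth), 0.05 * truth)
})

test_that("estimates are invariant to row order", {
  d <- sim_logistic(800, log(1.5), 77)
  r1 <- fit_adjusted_model(d, outcome = "y", predictors = "x",
                           covariates = "age", kind = "logistic")
  r2 <- fit_adjusted_model(d[sample(nrow(d)), ], outcome = "y", predictors = "x",
                           covariates = "age", kind = "logistic")
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)
})

test_that("risk surfaces are probabilities, monotone in horizon and track severity", {
  co <- generate_cohort(800, seed = 12, waveforms = "none")
  out <- co$outcomes
  # severity correlates with dim1 by construction of this surrogate tree
  n <- nrow(out)
  Z <- rbind(2 * (out$severity - 0.5) + rnorm(n, 0, 0.2), rnorm(n, 0, 0.5))
  K <- 20
  model <- structure(list(X = t(Z), W = diag(2), Z = Z, Y = Z[, 1:K],
                          B = mst_oracle_adjacency(Z[, 1:K]),
                          R = diag(n)[, 1:K],
                          centroid = rep(seq_len(K), length.out = n),
                          objective = 0, converged = TRUE),
                     class = "tree_model")
  model <- compute_pseudotime(assign_branches(model))

  p1 <- risk_surface(model, out, kind = "fine_gray", horizon = 500)
  p2 <- risk_surface(model, out, kind = "fine_gray", horizon = 1500)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_true(all(p2 >= p1 - 1e-12))
  expect_gt(cor(p2, out$severity, method = "spearman"), 0.5)

  p_cox <- risk_surface(model, out, kind = "cox", horizon = 1000)
  expect_true(all(p_cox >= 0 & p_cox <= 1))

  # null generator: flat surface
  co0 <- generate_cohort(800, synthetic_outcome_spec(log_hr_per_severity = 0),
                         seed = 13, waveforms = "none")
  Z0 <- rbind(rnorm(n), rnorm(n))
  model0 <- structure(list(X = t(Z0), W = diag(2), Z = Z0, Y = Z0[, 1:K],
                           B = mst_oracle_adjacency(Z0[, 1:K]),
                           R = diag(n)[, 1:K],
                           centroid = rep(seq_len(K), length.out = n),
                           objective = 0, converged = TRUE),
                      class = "tree_model")
  model0 <- compute_pseudotime(assign_branches(model0))
  p0 <- risk_surface(model0, co0$outcomes, kind = "fine_gray", horizon = 1000)
  expect_lt(sd(p0), 0.2 * mean(p0))

  expect_warning(risk_surface(model, out, kind = "cox",
                              horizon = max(out$time_to_event) + 10),
                 "extrapolating")
})

test_that("Moran's I matches its analytic null and the ape oracle", {
  set.seed(5)
  n <- 120
  coords <- cbind(runif(n), runif(n))
  vals <- rnorm(n)
  res <- morans_i(vals, coords, k_neighbors = 8, n_perm = 499, seed = 1)
  expect_equal(res$expected_I, -1 / (n - 1))
  # permutation null mean within 2 Monte Carlo SEs of -1/(N-1)
  mc_se <- sd(res$perm) / sqrt(length(res$perm))
  expect_lt(abs(mean(res$perm) - (-1 / (n - 1))), 2 * mc_se + 1e-12)

  # oracle: ape::Moran.I with the same row-standardized kNN weights
  D <- as.matrix(dist(coords))
  diag(D) <- Inf
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, order(D[i, ])[1:8]] <- 1 / 8
  ape_res <- ape::Moran.I(vals, W, scaled = FALSE)
  expect_equal(res$I, ape_res$observed, tolerance = 1e-10)

  expect_error(morans_i(rep(1, n), coords), class = "phenotree_constant_values")
})

test_that("a planted two-cluster field shows strong autocorrelation", {
  set.seed(6)
  n <- 150
  coords <- rbind(cbind(rnorm(n / 2, -3, 0.5), rnorm(n / 2, 0, 0.5)),
                  cbind(rnorm(n / 2, 3, 0.5), rnorm(n / 2, 0, 0.5)))
  vals <- rep(c(0, 1), each = n / 2)
  res <- morans_i(vals, coords, n_perm = 999, seed = 2)
  expect_gte(res$I, 0.8)
  expect_lte(res$p_perm, 0.01)
})

test_that("elastic-net explainability recovers a planted feature", {
  set.seed(21)
  n <- 400
  X <- matrix(rnorm(n * 20), n, 20)
  colnames(X) <- paste0("z", 1:20)
  grp <- ifelse(X[, 7] > 0, 1L, 2L)
  res <- explain_phenogroups(X, grp, seed = 3)
  top1 <- res[res$phenogroup == 1 & res$rank == 1, ]
  expect_equal(top1$feature, "z7")
  expect_equal(nrow(res[res$phenogroup == 1, ]), 3)   # top 3 reported

  # random labels: the cross-validated penalty shrinks everything away
  grp_rand <- sample(1:2, n, replace = TRUE)
  res_rand <- explain_phenogroups(X, grp_rand, seed = 4)
  expect_lte(sum(res_rand$n_nonzero), 4)

  expect_error(explain_phenogroups(X, rep(1, n)), "at least 2")
})

test_that("prognostic model comparison separates signal from noise", {
  co <- generate_cohort(2000, synthetic_outcome_spec(log_hr_per_severity = 2),
                        seed = 31, waveforms = "none")
  d <- co$outcomes
  set.seed(32)
  d$noise <- rnorm(nrow(d))
  cmp <- compare_prognostic_models(d, terms_A = "severity", terms_B = "noise",
                                   n_boot = 100, seed = 33)
  expect_gt(cmp$c_index_A, cmp$c_index_B)
  expect_gte(mean(cmp$boot[1, ] > cmp$boot[2, ], na.rm = TRUE), 0.95)
  expect_gt(cmp$z, 0)

  # self-comparison is exactly neutral
  self <- compare_prognostic_models(d, terms_A = "severity", terms_B = "severity",
                                    n_boot = 20, seed = 34)
  expect_equal(self$z, 0)
  expect_equal(self$c_index_A, self$c_index_B)

  # chance-level concordance for a pure-noise predictor
  cfit <- survival::coxph(survival::Surv(time_to_event, event_indicator == 1) ~
                            noise, data = d)
  cc <- as.numeric(survival::concordance(cfit)$concordance)
  expect_lt(abs(cc - 0.5), 0.03)

  nodata <- d
  nodata$event_indicator <- 0
  expect_error(compare_prognostic_models(nodata, "severity", "noise", n_boot = 5),
               "no events")
})

test_that("Benjamini-Hochberg adjustment matches the step-up construction", {
  one <- tibble::tibble(p = 0.03)
  expect_equal(adjust_pvalues(one)$q, 0.03)
  four <- tibble::tibble(p = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(adjust_pvalues(four)$q, rep(0.04, 4))
  ones <- tibble::tibble(p = rep(1, 5))
  expect_equal(adjust_pvalues(ones)$q, rep(1, 5))
  mixed <- tibble::tibble(p = runif(20))
  adj <- adjust_pvalues(mixed)
  expect_true(all(adj$q >= adj$p))
})

test_that("singular and separated fits fail loudly", {
  d <- sim_logistic(200, 0.5, 9)
  d$x2 <- d$x                                   # aliased copy
  expect_error(fit_adjusted_model(d, outcome = "y", predictors = c("x", "x2"),
                                  covariates = character(0), kind = "logistic"),
               "singular")
  d2 <- data.frame(y = rep(0:1, each = 50), x = rep(c(-1, 1), each = 50))
  expect_error(suppressWarnings(
    fit_adjusted_model(d2, outcome = "y", predictors = "x",
                       covariates = character(0), kind = "logistic")),
    "separation|converge")
})
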