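# Statistical overlays on the tree: adjusted regression models (logistic,
# linear, Cox, Fine-Gray), per-sample risk surfaces, Global Moran's I,
# elastic-net explainability, prognostic model comparison and
# multiple-testing adjustment.

DEFAULT_COVARIATES <- c("age", "sex", "heart_rate", "qtc_ms", "qrs_ms", "morphology")

tidy_fit <- function(fit, kind, n, events = NA_integer_) {
  co <- coef(fit)
  if (anyNA(co)) stopf("model is singular (aliased terms: %s)",
                       paste(names(co)[is.na(co)], collapse = ", "))
  se <- sqrt(diag(vcov(fit)))
  if (kind %in% c("logistic", "cox", "fine_gray") && any(abs(co) > 15))
    stopf("apparent separation: |coefficient| > 15 on the log scale for %s",
          paste(names(co)[abs(co) > 15], collapse = ", "))
  keep <- names(co) != "(Intercept)"
  est <- co[keep]
  se <- se[keep]
  zv <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    exp_estimate = unname(exp(est)),
    ci_low = unname(exp(est - 1.96 * se)),
    ci_high = unname(exp(est + 1.96 * se)),
    p = unname(2 * pnorm(-abs(zv))),
    n = n, events = events, model_kind = kind)
}

#' Fit a covariate-adjusted association model
#'
#' One interface for the four model families used across the analysis:
#' logistic or linear regression for prevalent/continuous outcomes, Cox
#' proportional hazards for fatal endpoints, and the Fine-Gray
#' subdistribution-hazard model for nonfatal endpoints with death as the
#' competing event (fitted as a weighted Cox model on the
#' [survival::finegray()] expansion, the censoring-weighted risk-set
#' construction of Fine & Gray). Estimates are Wald-based; exponentiated
#' estimates are odds/hazard/subdistribution-hazard ratios. Complete cases
#' only; the number dropped is reported as an attribute.
#'
#' @param data data frame / tibble, one row per ECG.
#' @param outcome outcome column (logistic/linear); ignored for survival
#'   kinds, which use `time_col`/`event_col`.
#' @param predictors character vector of predictor columns (e.g.
#'   `"phenogroup"` or tree dimensions).
#' @param covariates adjustment covariates; defaults to age, sex, heart
#'   rate, QTc, QRS duration and QRS morphology.
#' @param kind `"logistic"`, `"linear"`, `"cox"` or `"fine_gray"`.
#' @param ref_phenogroup reference level used when `phenogroup` is a
#'   predictor (the average branch serves as baseline comparator).
#' @param time_col,event_col survival columns; `event_col` codes
#'   0 = censored, 1 = event, 2 = competing death.
#' @return tibble with term, estimate (log scale), exp_estimate, 95% CI,
#'   p, n, events and model_kind.
#' @export
fit_adjusted_model <- function(data, outcome = NULL, predictors,
                               covariates = DEFAULT_COVARIATES,
                               kind = c("logistic", "linear", "cox", "fine_gray"),
                               ref_phenogroup = 4,
                               time_col = "time_to_event",
                               event_col = "event_indicator") {
  kind <- match.arg(kind)
  covariates <- intersect(covariates, names(data))
  rhs_vars <- c(predictors, covariates)
  need <- switch(kind, logistic = , linear = c(outcome, rhs_vars),
                 c(time_col, event_col, rhs_vars))
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  d <- as.data.frame(data)[, need, drop = FALSE]
  cc <- complete.cases(d)
  d <- d[cc, , drop = FALSE]
  if ("phenogroup" %in% names(d)) {
    d$phenogroup <- factor(d$phenogroup)
    if (as.character(ref_phenogroup) %in% levels(d$phenogroup))
      d$phenogroup <- stats::relevel(d$phenogroup, ref = as.character(ref_phenogroup))
  }
  rhs <- paste(rhs_vars, collapse = " + ")
  n <- nrow(d)

  res <- switch(kind,
    logistic = {
      fit <- glm(as.formula(paste(outcome, "~", rhs)), data = d, family = binomial())
      if (!fit$converged) stopf("logistic fit did not converge (possible separation)")
      tidy_fit(fit, kind, n, events = sum(d[[outcome]] %in% c(1, TRUE)))
    },
    linear = {
      fit <- lm(as.formula(paste(outcome, "~", rhs)), data = d)
      out <- tidy_fit(fit, kind, n)
      # linear estimates are already on the outcome scale; CIs likewise
      se <- sqrt(diag(vcov(fit)))[names(coef(fit)) != "(Intercept)"]
      out$exp_estimate <- out$estimate
      out$ci_low <- out$estimate - 1.96 * se
      out$ci_high <- out$estimate + 1.96 * se
      out
    },
    cox = {
      fit <- survival::coxph(
        as.formula(paste0("survival::Surv(", time_col, ", ", event_col, " == 1) ~ ", rhs)),
        data = d)
      tidy_fit(fit, kind, n, events = sum(d[[event_col]] == 1))
    },
    fine_gray = {
      d$.evf <- factor(d[[event_col]], levels = c(0, 1, 2),
                       labels = c("censor", "event", "death"))
      fg <- survival::finegray(
        as.formula(paste0("survival::Surv(", time_col, ", .evf) ~ .")),
        data = d, etype = "event")
      fit <- survival::coxph(
        as.formula(paste("survival::Surv(fgstart, fgstop, fgstatus) ~", rhs)),
        data = fg, weights = fgwt)
      tidy_fit(fit, kind, n, events = sum(d[[event_col]] == 1))
    })
  attr(res, "n_dropped") <- sum(!cc)
  res
}

#' Per-sample predicted event probabilities over the tree
#'
#' Fits a survival model on the two tree dimensions and global pseudotime
#' (Cox for fatal endpoints; Fine-Gray with death competing for nonfatal
#' ones) and returns each sample's predicted cumulative incidence at a
#' horizon (default: median follow-up).
#'
#' @param tree a fitted tree with pseudotime ([compute_pseudotime()]).
#' @param data outcome table aligned row-for-row with the tree's samples.
#' @param kind `"cox"` or `"fine_gray"`.
#' @param horizon horizon in days; defaults to median follow-up.
#' @param time_col,event_col survival columns as in [fit_adjusted_model()].
#' @return numeric vector of probabilities in `[0, 1]`, one per sample;
#'   attributes carry the horizon and the fitted model.
#' @export
risk_surface <- function(tree, data, kind = c("cox", "fine_gray"),
                         horizon = NULL, time_col = "time_to_event",
                         event_col = "event_indicator") {
  kind <- match.arg(kind)
  stopifnot(inherits(tree, "tree_model"))
  if (is.null(tree$pseudotime_global)) stopf("run compute_pseudotime() first")
  if (nrow(data) != ncol(tree$Z)) stopf("data rows must match tree samples")
  d <- data.frame(dim1 = tree$Z[1, ], dim2 = tree$Z[2, ],
                  pseudotime = tree$pseudotime_global,
                  time = data[[time_col]], ev = data[[event_col]])
  horizon <- horizon %||% median(d$time)
  if (horizon > max(d$time))
    warnf("horizon %.0f beyond the observed range %.0f; extrapolating", horizon, max(d$time))
  if (kind == "cox") {
    fit <- survival::coxph(survival::Surv(time, ev == 1) ~ dim1 + dim2 + pseudotime,
                           data = d)
  } else {
    d$.evf <- factor(d$ev, levels = c(0, 1, 2), labels = c("censor", "event", "death"))
    fg <- survival::finegray(survival::Surv(time, .evf) ~ ., data = d, etype = "event")
    fit <- survival::coxph(survival::Surv(fgstart, fgstop, fgstatus) ~
                             dim1 + dim2 + pseudotime, data = fg, weights = fgwt)
  }
  bh <- survival::basehaz(fit, centered = FALSE)
  H0 <- stats::approxfun(c(0, bh$time), c(0, bh$hazard), method = "constant",
                         rule = 2, f = 0)
  lp <- as.numeric(predict(fit, newdata = d, type = "lp", reference = "zero"))
  p <- 1 - exp(-H0(horizon) * exp(lp))
  attr(p, "horizon") <- horizon
  attr(p, "fit") <- fit
  p
}

#' Global Moran's I on tree coordinates
#'
#' Spatial autocorrelation of a per-sample variable over a row-standardized
#' k-nearest-neighbour weight graph built from the embedding coordinates,
#' with a permutation null.
#'
#' @param values numeric (or 0/1) per-sample values; must not be constant.
#' @param coords N x 2 coordinate matrix (tree dimensions).
#' @param k_neighbors neighbours per sample.
#' @param n_perm permutations for the p-value.
#' @param seed RNG seed for the permutations.
#' @return list: `I`, `expected_I` (-1/(N-1)), `p_perm` (upper tail),
#'   `perm` (the permuted statistics).
#' @export
morans_i <- function(values, coords, k_neighbors = 8, n_perm = 999, seed = 1) {
  values <- as.numeric(values)
  coords <- as.matrix(coords)
  N <- length(values)
  if (N < 10) stopf("need at least 10 samples")
  if (nrow(coords) != N) stopf("coords rows must match length(values)")
  if (sd(values) == 0)
    stop(structure(class = c("phenotree_constant_values", "error", "condition"),
                   list(message = "Moran's I undefined for constant values", call = NULL)))
  D <- sqdist_cols(t(coords), t(coords))
  diag(D) <- Inf
  nb <- t(apply(D, 1, function(r) order(r)[seq_len(k_neighbors)]))
  stat <- function(z) {
    zc <- z - mean(z)
    lag <- rowMeans(matrix(zc[nb], N))            # row-standardized W %*% z
    sum(zc * lag) / sum(zc^2)                     # S0 = N cancels
  }
  I_obs <- stat(values)
  perm <- with_seed(seed,
    vapply(seq_len(n_perm), function(b) stat(sample(values)), numeric(1)))
  list(I = I_obs, expected_I = -1 / (N - 1),
       p_perm = (1 + sum(perm >= I_obs)) / (n_perm + 1),
       perm = perm)
}

#' Elastic-net explainability of phenogroups
#'
#' One-vs-rest elastic-net logistic regression of the latent features on
#' each phenogroup; the penalty mixing (alpha) and strength (lambda) are
#' chosen by cross-validation, and the strongest nonzero coefficients are
#' reported (3 per phenogroup by convention).
#'
#' @param latents N x d latent feature matrix.
#' @param phenogroup per-sample labels.
#' @param alpha_grid elastic-net mixing values searched.
#' @param n_top features reported per phenogroup.
#' @param nfolds cross-validation folds.
#' @param seed RNG seed (fold assignment).
#' @return tibble: phenogroup, rank, feature, coefficient (standardized
#'   scale), alpha, n_nonzero.
#' @export
explain_phenogroups <- function(latents, phenogroup, alpha_grid = c(0.2, 0.5, 0.8),
                                n_top = 3, nfolds = 5, seed = 1) {
  X <- standardize_columns(as.matrix(latents))
  if (is.null(colnames(X))) colnames(X) <- paste0("z", seq_len(ncol(X)))
  groups <- sort(unique(phenogroup))
  if (length(groups) < 2) stopf("need at least 2 phenogroups")
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), nrow(X))))
  out <- lapply(groups, function(g) {
    y <- as.integer(phenogroup == g)
    if (sum(y) < nfolds || sum(1 - y) < nfolds)
      stopf("phenogroup %s too small for cross-validated fitting", g)
    fits <- lapply(alpha_grid, function(a)
      glmnet::cv.glmnet(X, y, family = "binomial", alpha = a,
                        foldid = foldid, standardize = FALSE))
    cvm <- vapply(fits, function(f) min(f$cvm), numeric(1))
    best <- fits[[which.min(cvm)]]
    beta <- as.numeric(coef(best, s = "lambda.min"))[-1]
    nz <- which(beta != 0)
    ord <- nz[order(abs(beta[nz]), decreasing = TRUE)]
    take <- head(ord, n_top)
    if (!length(take))
      return(tibble::tibble(phenogroup = g, rank = integer(0), feature = character(0),
                            coefficient = numeric(0), alpha = numeric(0),
                            n_nonzero = integer(0)))
    tibble::tibble(phenogroup = g, rank = seq_along(take),
                   feature = colnames(X)[take], coefficient = beta[take],
                   alpha = alpha_grid[which.min(cvm)], n_nonzero = length(nz))
  })
  do.call(rbind, out)
}

# Per-subject Breslow log-partial-likelihood contributions at the fitted lp.
cox_pl_contributions <- function(time, event, lp) {
  n <- length(time)
  l <- numeric(n)
  riskset <- vapply(seq_len(n), function(i) sum(exp(lp[time >= time[i]])), numeric(1))
  ev <- event == 1 | event == TRUE
  l[ev] <- lp[ev] - log(riskset[ev])
  l
}

#' Compare two Cox prognostic models
#'
#' Bootstrapped Harrell's C-index (mean and SD over refits on resamples)
#' for two covariate sets fitted to the same rows, plus a Vuong-type
#' comparison of fit built from per-subject log-partial-likelihood
#' contributions of the two (possibly non-nested) models.
#'
#' @param data outcome table.
#' @param terms_A,terms_B character vectors of covariate names.
#' @param n_boot bootstrap iterations (1000 by convention).
#' @param seed RNG seed.
#' @param time_col,event_col survival columns (events are `event_col == 1`).
#' @return list: `c_index_A`, `sd_A`, `c_index_B`, `sd_B`, `z`, `p`.
#' @export
compare_prognostic_models <- function(data, terms_A, terms_B, n_boot = 1000,
                                      seed = 1, time_col = "time_to_event",
                                      event_col = "event_indicator") {
  vars <- unique(c(terms_A, terms_B, time_col, event_col))
  d <- as.data.frame(data)[, vars, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  d$.ev <- d[[event_col]] == 1
  if (!any(d$.ev)) stopf("no events in the data")
  f_A <- as.formula(paste0("survival::Surv(", time_col, ", .ev) ~ ",
                           paste(terms_A, collapse = " + ")))
  f_B <- as.formula(paste0("survival::Surv(", time_col, ", .ev) ~ ",
                           paste(terms_B, collapse = " + ")))
  fit_A <- survival::coxph(f_A, data = d)
  fit_B <- survival::coxph(f_B, data = d)

  cidx <- function(fit) as.numeric(survival::concordance(fit)$concordance)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(d), replace = TRUE)
      db <- d[idx, , drop = FALSE]
      c(tryCatch(cidx(survival::coxph(f_A, data = db)), error = function(e) NA_real_),
        tryCatch(cidx(survival::coxph(f_B, data = db)), error = function(e) NA_real_))
    }, numeric(2))
  })
  lp_A <- as.numeric(predict(fit_A, type = "lp", reference = "zero"))
  lp_B <- as.numeric(predict(fit_B, type = "lp", reference = "zero"))
  dl <- cox_pl_contributions(d[[time_col]], d$.ev, lp_A) -
        cox_pl_contributions(d[[time_col]], d$.ev, lp_B)
  z <- if (sd(dl) < 1e-12) 0 else sqrt(nrow(d)) * mean(dl) / sd(dl)
  list(c_index_A = mean(boots[1, ], na.rm = TRUE), sd_A = sd(boots[1, ], na.rm = TRUE),
       c_index_B = mean(boots[2, ], na.rm = TRUE), sd_B = sd(boots[2, ], na.rm = TRUE),
       z = z, p = 2 * pnorm(-abs(z)), boot = boots)
}

#' Adjust a results table for multiple testing
#'
#' @param results a tibble with a `p` column (as returned by
#'   [fit_adjusted_model()]), or several row-bound together.
#' @param method adjustment method passed to [stats::p.adjust()]
#'   (Benjamini-Hochberg by default).
#' @return the table with a `q` column appended (`q >= p`, order-preserving).
#' @export
adjust_pvalues <- function(results, method = "BH") {
  if (!"p" %in% names(results)) stopf("results lack a 'p' column")
  results$q <- p.adjust(results$p, method = method)
  results
}
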