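# Projection of new cohorts onto a frozen reference tree: gradient-boosted
# coordinate regression, nearest-point-on-tree snapping, and k-NN
# phenogroup classification with a cross-validated k.

#' Fit a projection model from a frozen reference tree
#'
#' Trains two independent gradient-boosted (XGBoost) regressors mapping the
#' reference cohort's latent features to its two tree coordinates, records
#' validation R-squared and mean absolute error on a held-out split, and
#' selects the neighbourhood size of the phenogroup k-NN classifier by
#' 10-fold cross-validation over a 1-200 grid scored by macro F1 (ties go
#' to the smallest k).
#'
#' @param reference a fitted [fit_ddrtree()] model carrying phenogroup
#'   labels ([merge_branches()]).
#' @param split train fraction of the 75:25-style split, in (0, 1).
#' @param k_grid candidate neighbour counts for the classifier.
#' @param nrounds,max_depth,eta XGBoost schedule for both regressors.
#' @param seed RNG seed (split, folds, XGBoost).
#' @return an object of class `projection_model`: `coord_regressors`,
#'   `knn` (reference coordinates + labels + selected k), `train_metrics`
#'   (r2/mae per dimension) and the frozen `reference` geometry (edges and
#'   node coordinates only).
#' @export
fit_projection <- function(reference, split = 0.75, k_grid = 1:200,
                           nrounds = 150, max_depth = 4, eta = 0.1, seed = 1) {
  stopifnot(inherits(reference, "tree_model"))
  if (!(split > 0 && split < 1)) stopf("split must be in (0, 1)")
  if (is.null(reference$phenogroup))
    stopf("reference tree has no phenogroups; run merge_branches() first")
  X <- unclass(reference$X)
  attr(X, "scaled:center") <- NULL
  N <- nrow(X)
  dims <- t(reference$Z)
  colnames(dims) <- c("dim1", "dim2")
  labels <- reference$phenogroup

  idx_train <- with_seed(seed, sort(sample.int(N, round(split * N))))
  idx_val <- setdiff(seq_len(N), idx_train)

  fit_one <- function(y) {
    with_seed(seed, xgboost::xgboost(
      X[idx_train, , drop = FALSE], y[idx_train],
      nrounds = nrounds, max_depth = max_depth, learning_rate = eta,
      nthreads = 1, verbosity = 0, objective = "reg:squarederror"))
  }
  metrics_one <- function(fit, y) {
    pred <- predict(fit, X[idx_val, , drop = FALSE])
    list(r2 = 1 - sum((y[idx_val] - pred)^2) / sum((y[idx_val] - mean(y[idx_val]))^2),
         mae = mean(abs(y[idx_val] - pred)))
  }
  reg1 <- fit_one(dims[, 1])
  reg2 <- fit_one(dims[, 2])
  m1 <- metrics_one(reg1, dims[, 1])
  m2 <- metrics_one(reg2, dims[, 2])

  k_sel <- select_knn_k(dims[idx_train, , drop = FALSE], labels[idx_train],
                        k_grid = k_grid, n_folds = 10, seed = seed)

  structure(list(
    coord_regressors = list(dim1 = reg1, dim2 = reg2),
    knn = list(coords = dims, labels = labels, k = k_sel$k, cv = k_sel$score),
    train_metrics = list(r2_dim1 = m1$r2, mae_dim1 = m1$mae,
                         r2_dim2 = m2$r2, mae_dim2 = m2$mae),
    reference = list(Y = reference$Y, edges = tree_edges(reference$B)),
    n_features = ncol(X), split = split, seed = seed,
    train_idx = idx_train, holdout_idx = idx_val),
    class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model> R2 dim1 %.3f / dim2 %.3f (MAE %.3f / %.3f), k-NN k = %d\n",
              x$train_metrics$r2_dim1, x$train_metrics$r2_dim2,
              x$train_metrics$mae_dim1, x$train_metrics$mae_dim2, x$knn$k))
  invisible(x)
}

# Deterministic k-NN vote: majority over the k nearest training points,
# ties broken by smallest mean neighbour distance, then lowest label.
knn_predict <- function(train_xy, train_lab, test_xy, k) {
  D <- sqdist_cols(t(test_xy), t(train_xy))       # n_test x n_train
  k <- min(k, ncol(D))
  labs <- sort(unique(train_lab))
  out <- integer(nrow(D))
  for (i in seq_len(nrow(D))) {
    ord <- order(D[i, ])[seq_len(k)]
    v <- train_lab[ord]
    tab <- table(factor(v, levels = labs))
    top <- labs[tab == max(tab)]
    if (length(top) > 1L) {
      md <- vapply(top, function(l) mean(D[i, ord][v == l]), numeric(1))
      top <- top[order(md, top)][1]
    }
    out[i] <- top
  }
  out
}

# 10-fold CV over the k grid, scored by macro F1; one neighbour ordering
# per fold serves every k.
select_knn_k <- function(xy, lab, k_grid = 1:200, n_folds = 10, seed = 1) {
  n <- nrow(xy)
  k_max_usable <- max(2L, floor(n * (n_folds - 1) / n_folds) - 1L)
  if (max(k_grid) > k_max_usable) {
    k_grid <- k_grid[k_grid <= k_max_usable]
    warnf("k grid truncated at %d (limited training-fold size)", k_max_usable)
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  labs <- sort(unique(lab))
  score <- matrix(0, length(k_grid), n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    D <- sqdist_cols(t(xy[!tr, , drop = FALSE]), t(xy[tr, , drop = FALSE]))
    ordm <- t(apply(D, 1, order))[, seq_len(min(max(k_grid), sum(tr))), drop = FALSE]
    nl <- matrix(lab[tr][ordm], nrow(ordm))
    truth <- lab[!tr]
    for (ki in seq_along(k_grid)) {
      k <- k_grid[ki]
      pred <- apply(nl[, seq_len(k), drop = FALSE], 1, function(v) {
        tab <- table(factor(v, levels = labs))
        labs[which.max(tab)]
      })
      score[ki, f] <- macro_f1(truth, pred, labs)
    }
  }
  mean_score <- rowMeans(score)
  k <- k_grid[which.max(mean_score)]     # first max -> smallest k on ties
  list(k = k, score = setNames(mean_score, k_grid))
}

macro_f1 <- function(truth, pred, labs) {
  f1 <- vapply(labs, function(l) {
    tp <- sum(pred == l & truth == l)
    fp <- sum(pred == l & truth != l)
    fn <- sum(pred != l & truth == l)
    if (tp == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

#' Snap points to the nearest point on a tree
#'
#' Orthogonal projection of each point onto every backbone segment, taking
#' the minimum over segments (endpoints included), so the snapped distance
#' to the tree is exact.
#'
#' @param points n x 2 matrix of raw coordinates.
#' @param Y 2 x K node coordinate matrix.
#' @param edges integer matrix of tree edges (rows: node index pairs).
#' @return list with `snapped` (n x 2) and `dist` (Euclidean distance moved).
#' @export
snap_to_tree <- function(points, Y, edges) {
  points <- matrix(points, ncol = 2)
  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  snapped <- matrix(NA_real_, n, 2)
  for (e in seq_len(nrow(edges))) {
    a <- Y[, edges[e, 1]]
    b <- Y[, edges[e, 2]]
    ab <- b - a
    len2 <- sum(ab^2)
    tpar <- if (len2 == 0) rep(0, n) else
      pmin(1, pmax(0, ((points[, 1] - a[1]) * ab[1] + (points[, 2] - a[2]) * ab[2]) / len2))
    px <- a[1] + tpar * ab[1]
    py <- a[2] + tpar * ab[2]
    d2 <- (points[, 1] - px)^2 + (points[, 2] - py)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    snapped[upd, ] <- cbind(px, py)[upd, , drop = FALSE]
  }
  list(snapped = snapped, dist = sqrt(best_d2))
}

#' Project an external cohort onto the reference tree
#'
#' Predicts raw tree coordinates from latent features with the frozen
#' regressors, snaps them to the nearest point on the reference backbone,
#' and assigns phenogroups by k-NN vote among the reference samples in
#' coordinate space. The reference tree itself is never refit.
#'
#' @param model a [fit_projection()] model.
#' @param features M x d latent-feature matrix (same columns as the
#'   reference features).
#' @return tibble: id, dim1_raw, dim2_raw, dim1_snap, dim2_snap,
#'   snap_dist, phenogroup.
#' @export
project_cohort <- function(model, features) {
  stopifnot(inherits(model, "projection_model"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stopf("feature dimension %d does not match the reference's %d",
          ncol(features), model$n_features)
  raw <- cbind(predict(model$coord_regressors$dim1, features),
               predict(model$coord_regressors$dim2, features))
  sn <- snap_to_tree(raw, model$reference$Y, model$reference$edges)
  grp <- knn_predict(model$knn$coords, model$knn$labels, sn$snapped, model$knn$k)
  tibble::tibble(id = rownames(features) %||% sprintf("ext%05d", seq_len(nrow(raw))),
                 dim1_raw = raw[, 1], dim2_raw = raw[, 2],
                 dim1_snap = sn$snapped[, 1], dim2_snap = sn$snapped[, 2],
                 snap_dist = sn$dist, phenogroup = grp)
}
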