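# Reversed graph embedding (DDRTree), implemented from scratch.
#
# Given standardized features X (d x N), the method jointly learns an
# orthonormal basis W (d x 2), embedded sample coordinates Z (2 x N),
# centroid coordinates Y (2 x K), a spanning tree B over the centroids and
# soft sample-centroid assignments R (N x K) by alternating minimization of
#
#   f = ||X - W Z||^2 + lambda * sum_{(i,j) in B} ||y_i - y_j||^2
#     + gamma * [ sum_ik R_ik ||z_i - y_k||^2 + sigma * sum_ik R_ik log R_ik ]
#
# Each block update is an exact minimizer, so the objective is
# non-increasing across iterations:
#   B: minimum spanning tree over centroid distances;
#   R: row-wise softmax of -||z_i - y_k||^2 / sigma;
#   (W, Z, Y): closed form — Y = Z R M^{-1} with M = (lambda/gamma) L + Gamma
#     (L the tree Laplacian, Gamma = diag(colSums R)); eliminating Y and Z
#     reduces the problem to maximizing tr(W' X A^{-1} X' W) with
#     A = (1+gamma) I - gamma R M^{-1} R', solved by the top eigenvectors of
#     X A^{-1} X' (A^{-1} applied via the Woodbury identity so nothing
#     N x N is ever formed).

#' DDRTree hyperparameters
#'
#' "Standard parameters" follow common convention: `lambda = 5 * N / K`
#' when left `NULL`, `sigma = 1e-3`, `gamma = 10`.
#'
#' @param K number of centroids (clamped to N with a warning when larger).
#' @param lambda tree-smoothness weight; `NULL` for the `5 * N / K` default.
#' @param sigma Boltzmann bandwidth of the soft assignments.
#' @param gamma data-centroid attraction weight.
#' @param max_iter maximum alternating-minimization iterations.
#' @param tol relative objective change declaring convergence.
#' @param n_dims embedding dimensionality (2 for trees; untested beyond 2).
#' @return list of hyperparameters.
#' @export
ddrtree_params <- function(K = 2000, lambda = NULL, sigma = 1e-3, gamma = 10,
                           max_iter = 20, tol = 1e-3, n_dims = 2) {
  list(K = as.integer(K), lambda = lambda, sigma = sigma, gamma = gamma,
       max_iter = as.integer(max_iter), tol = tol, n_dims = as.integer(n_dims))
}

# Dense squared Euclidean distance between column sets (2 x n matrices).
sqdist_cols <- function(A, B) {
  an <- colSums(A^2)
  bn <- colSums(B^2)
  d <- outer(an, bn, "+") - 2 * crossprod(A, B)
  d[d < 0] <- 0
  d
}

# Prim's algorithm on a dense symmetric weight matrix; deterministic
# tie-breaking by lowest index (which.min picks the first minimum).
mst_prim <- function(D) {
  K <- nrow(D)
  if (K == 1L) return(matrix(0, 1, 1))
  in_tree <- logical(K)
  in_tree[1] <- TRUE
  best_w <- D[, 1]
  best_from <- rep(1L, K)
  B <- matrix(0, K, K)
  for (step in seq_len(K - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_w[cand])]
    i <- best_from[j]
    B[i, j] <- B[j, i] <- 1
    in_tree[j] <- TRUE
    upd <- !in_tree & D[, j] < best_w
    best_w[upd] <- D[upd, j]
    best_from[upd] <- j
  }
  B
}

tree_edges <- function(B) {
  e <- which(B != 0 & upper.tri(B), arr.ind = TRUE)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Fit a DDRTree model
#'
#' @param X numeric matrix, samples x features. Columns are standardized
#'   (zero mean, unit variance) internally before fitting; the standardized
#'   copy is kept in the model for projection learning.
#' @param params hyperparameters from [ddrtree_params()].
#' @param seed seed for the centroid initialization (distinct seeded sample
#'   of embedded points).
#' @param standardize standardize columns before fitting (recommended for
#'   heterogeneous features such as VAE latents). Disable for inputs already
#'   on a common scale; the fit is then exactly equivariant to orthogonal
#'   rotations of the feature space.
#' @return an object of class `tree_model` with elements `X` (standardized
#'   features), `W` (orthonormal basis), `Z` (2 x N embedding, also exposed
#'   as `dim1`/`dim2` in [tree_samples()]), `Y` (2 x K centroids), `B`
#'   (K x K spanning-tree adjacency), `R` (N x K soft assignments),
#'   `centroid` (argmax-R centroid per sample), `objective` (per-iteration
#'   trace), `converged`, and the hyperparameters.
#' @export
fit_ddrtree <- function(X, params = ddrtree_params(), seed = 1,
                        standardize = TRUE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stopf("non-finite values in feature matrix")
  N <- nrow(X)
  d <- ncol(X)
  if (N < 3) stopf("need at least 3 samples")
  if (params$K < 2) stopf("K must be >= 2")
  K <- params$K
  if (K > N) {
    warnf("K = %d exceeds N = %d; clamping to N", K, N)
    K <- N
  }
  lambda <- params$lambda %||% (5 * N / K)
  sigma <- params$sigma
  gamma <- params$gamma
  q <- params$n_dims

  Xs <- if (standardize) standardize_columns(X) else scale(X, scale = FALSE)
  Xt <- t(Xs)                                     # d x N

  # initialization: PCA basis, embedded coordinates, seeded distinct centroids
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  W <- pc$rotation[, seq_len(q), drop = FALSE]
  Z <- crossprod(W, Xt)                           # q x N
  Y <- with_seed(seed, Z[, sample.int(N, K), drop = FALSE])

  obj_trace <- numeric(0)
  converged <- FALSE
  B <- NULL
  R <- NULL

  update_BR <- function(Z, Y) {
    B <- mst_prim(sqdist_cols(Y, Y))
    D <- sqdist_cols(Z, Y)                        # N x K
    dmin <- D[cbind(seq_len(nrow(D)), max.col(-D, ties.method = "first"))]
    E <- exp(-(D - dmin) / sigma)
    R <- E / rowSums(E)
    list(B = B, R = R, D = D)
  }

  objective <- function(Z, Y, B, R, D) {
    L <- diag(colSums(B)) - B
    ent <- R * log(R)
    ent[!is.finite(ent)] <- 0                     # 0 log 0 = 0
    sum((Xt - W %*% Z)^2) +
      lambda * 0.5 * sum(B * sqdist_cols(Y, Y)) +
      gamma * (sum(R * D) + sigma * sum(ent))
  }

  for (it in seq_len(params$max_iter)) {
    br <- update_BR(Z, Y)
    B <- br$B; R <- br$R
    L <- diag(colSums(B)) - B
    Gam <- colSums(R)
    M <- (lambda / gamma) * L + diag(Gam)
    a <- 1 + gamma
    # A^{-1} via Woodbury: A = a I - gamma R M^{-1} R'
    RtR <- crossprod(R)                           # K x K
    inner <- M / gamma - RtR / a
    G <- tryCatch(solve(inner), error = function(e)
      solve(inner + diag(1e-8, K)))
    XR <- Xt %*% R                                # d x K
    XAinv <- (Xt + (XR %*% G) %*% t(R) / a) / a   # d x N
    S <- XAinv %*% t(Xt)                          # d x d
    eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
    W <- eg$vectors[, seq_len(q), drop = FALSE]
    Z <- crossprod(W, XAinv)                      # q x N
    Y <- t(solve(M, t(Z %*% R)))                  # q x K

    D <- sqdist_cols(Z, Y)
    obj <- objective(Z, Y, B, R, D)
    obj_trace <- c(obj_trace, obj)
    if (it > 1) {
      rel <- abs(obj_trace[it - 1] - obj) / max(1e-12, abs(obj_trace[it - 1]))
      if (rel < params$tol) { converged <- TRUE; break }
    }
  }
  if (!converged) warnf("DDRTree did not converge in %d iterations; returning best iterate",
                        params$max_iter)
  # leave B and R consistent with the final (Z, Y); both refreshes are exact
  # block minimizers, so the recorded objective still decreases
  br <- update_BR(Z, Y)
  B <- br$B; R <- br$R
  obj_trace <- c(obj_trace, objective(Z, Y, B, R, br$D))

  structure(list(
    X = Xs, W = W, Z = Z, Y = Y, B = B, R = R,
    centroid = max.col(R, ties.method = "first"),
    hyperparams = list(K = K, lambda = lambda, sigma = sigma, gamma = gamma,
                       max_iter = params$max_iter, tol = params$tol, n_dims = q,
                       seed = seed),
    objective = obj_trace, converged = converged,
    branch_id = NULL, phenogroup = NULL,
    pseudotime_global = NULL, pseudotime_branch = NULL),
    class = "tree_model")
}

#' @export
print.tree_model <- function(x, ...) {
  cat(sprintf("<tree_model> N = %d, K = %d, %s%s\n",
              ncol(x$Z), ncol(x$Y),
              if (x$converged) "converged" else "max_iter reached",
              if (!is.null(x$phenogroup))
                sprintf(", %d phenogroups", length(unique(x$phenogroup))) else ""))
  invisible(x)
}

tree_igraph <- function(model) {
  ed <- tree_edges(model$B)
  w <- sqrt(colSums((model$Y[, ed[, 1], drop = FALSE] -
                     model$Y[, ed[, 2], drop = FALSE])^2))
  igraph::graph_from_data_frame(
    data.frame(from = ed[, 1], to = ed[, 2], weight = w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(ncol(model$Y))))
}

#' Decompose the tree backbone into sub-branches
#'
#' Branch points are tree nodes of degree >= 3; a sub-branch is a maximal
#' path whose interior nodes all have degree 2, running between branch
#' points and/or leaves. Every edge belongs to exactly one sub-branch.
#' Centroids on a path interior inherit its branch; branch points and
#' leaves take the lowest-numbered incident branch. Samples inherit the
#' sub-branch of their argmax-assignment centroid.
#'
#' @param model a fitted [fit_ddrtree()] model.
#' @return the model with `branch_id` (per sample), `centroid_branch`
#'   (per centroid) and `branch_edges` filled in.
#' @export
assign_branches <- function(model) {
  stopifnot(inherits(model, "tree_model"))
  B <- model$B
  K <- nrow(B)
  ed <- tree_edges(B)
  deg <- colSums(B != 0)
  terminal <- which(deg != 2L)                    # leaves and branch points
  if (!length(terminal)) terminal <- 1L           # K == 1 or degenerate
  edge_id <- function(i, j) which((ed[, 1] == min(i, j)) & (ed[, 2] == max(i, j)))
  edge_branch <- rep(NA_integer_, nrow(ed))
  nb <- 0L
  for (s in terminal) {
    for (nbr in which(B[s, ] != 0)) {
      eid <- edge_id(s, nbr)
      if (!is.na(edge_branch[eid])) next
      nb <- nb + 1L
      prev <- s; cur <- nbr
      edge_branch[eid] <- nb
      while (deg[cur] == 2L) {
        nxt <- setdiff(which(B[cur, ] != 0), prev)
        edge_branch[edge_id(cur, nxt)] <- nb
        prev <- cur; cur <- nxt
      }
    }
  }
  centroid_branch <- rep(NA_integer_, K)
  for (v in seq_len(K)) {
    inc <- which(ed[, 1] == v | ed[, 2] == v)
    if (length(inc)) centroid_branch[v] <- min(edge_branch[inc])
  }
  if (any(is.na(centroid_branch))) centroid_branch[is.na(centroid_branch)] <- 1L
  model$branch_edges <- cbind(ed, branch = edge_branch)
  model$centroid_branch <- centroid_branch
  model$branch_id <- centroid_branch[model$centroid]
  model
}

#' Merge sub-branches into phenogroups
#'
#' Agglomerative merging of sub-branches by spatial proximity of their mean
#' coordinates in the 2-D embedding, using the size-weighted Ward cost
#' `n1 * n2 / (n1 + n2) * ||m1 - m2||^2` and restricted to pairs of
#' branches that are adjacent in the tree, so merged labels are always
#' contiguous along the backbone. The default of 6 groups reflects the
#' number of phenogroups the approach resolves on large broad-QRS cohorts;
#' the cut is a free parameter.
#'
#' @param model a [fit_ddrtree()] model with branches assigned (assigned
#'   on the fly if absent).
#' @param n_groups number of merged phenogroups; must not exceed the number
#'   of sub-branches.
#' @return the model with per-sample `phenogroup` and per-centroid
#'   `centroid_phenogroup` labels (integers 1..n_groups).
#' @export
merge_branches <- function(model, n_groups = 6) {
  stopifnot(inherits(model, "tree_model"))
  if (is.null(model$branch_id)) model <- assign_branches(model)
  nb <- max(model$branch_edges[, "branch"])
  branches <- seq_len(nb)
  if (n_groups > nb)
    stopf("n_groups = %d exceeds the %d available sub-branches", n_groups, nb)

  # cluster state: weight = samples on the branch (+1 so empty branches
  # still merge), mean = weighted mean of member samples' coordinates
  # (node coordinates for branches without samples)
  weight <- numeric(nb)
  means <- matrix(0, nb, 2)
  for (i in seq_len(nb)) {
    sel <- model$branch_id == i
    if (any(sel)) {
      weight[i] <- sum(sel) + 1
      means[i, ] <- rowMeans(model$Z[, sel, drop = FALSE])
    } else {
      nodes <- unique(as.vector(
        model$branch_edges[model$branch_edges[, "branch"] == i, 1:2]))
      weight[i] <- 1
      means[i, ] <- rowMeans(model$Y[, nodes, drop = FALSE])
    }
  }
  # branch adjacency: branches sharing a tree node
  adj <- matrix(FALSE, nb, nb)
  for (v in seq_len(nrow(model$B))) {
    inc <- unique(model$branch_edges[model$branch_edges[, 1] == v |
                                     model$branch_edges[, 2] == v, "branch"])
    for (a in inc) for (b in inc) if (a != b) adj[a, b] <- TRUE
  }
  active <- rep(TRUE, nb)
  members <- as.list(seq_len(nb))
  while (sum(active) > n_groups) {
    best <- c(NA, NA); best_cost <- Inf
    act <- which(active)
    for (i in act) for (j in act) if (i < j && adj[i, j]) {
      cost <- weight[i] * weight[j] / (weight[i] + weight[j]) *
        sum((means[i, ] - means[j, ])^2)
      if (cost < best_cost - 1e-15) { best_cost <- cost; best <- c(i, j) }
    }
    if (!is.finite(best_cost)) break   # adjacency exhausted (cannot occur on a tree)
    i <- best[1]; j <- best[2]
    w <- weight[i] + weight[j]
    means[i, ] <- (weight[i] * means[i, ] + weight[j] * means[j, ]) / w
    weight[i] <- w
    members[[i]] <- c(members[[i]], members[[j]])
    adj[i, ] <- adj[i, ] | adj[j, ]
    adj[, i] <- adj[, i] | adj[, j]
    adj[i, i] <- FALSE
    active[j] <- FALSE
  }
  map <- integer(nb)
  for (g in seq_along(which(active))) map[members[[which(active)[g]]]] <- g
  names(map) <- NULL
  lab <- setNames(map, branches)

  model$centroid_phenogroup <- unname(lab[as.character(model$centroid_branch)])
  model$phenogroup <- model$centroid_phenogroup[model$centroid]
  model$n_groups <- n_groups
  model
}

#' Compute pseudotime along the tree
#'
#' The tree center is the centroid nearest the grand mean of the embedded
#' coordinates. Global pseudotime of a sample is the geodesic distance
#' along the backbone (edge lengths Euclidean in the embedding) from the
#' center to the sample's centroid, plus the sample's Euclidean offset to
#' that centroid. Branch pseudotime is measured from the branch's node
#' nearest (in geodesic distance) to the center.
#'
#' @param model a [fit_ddrtree()] model (branches assigned on the fly if
#'   needed).
#' @return the model with `pseudotime_global`, `pseudotime_branch`,
#'   `center` (centroid index) and `centroid_pseudotime` filled in.
#' @export
compute_pseudotime <- function(model) {
  stopifnot(inherits(model, "tree_model"))
  if (is.null(model$branch_id)) model <- assign_branches(model)
  g <- tree_igraph(model)
  comp <- igraph::components(g)
  if (comp$no != 1L) stopf("tree backbone is disconnected — invariant violated")
  grand <- rowMeans(model$Z)
  center <- which.min(colSums((model$Y - grand)^2))
  dcen <- as.numeric(igraph::distances(g, v = as.character(center)))
  offset <- sqrt(rowSums((t(model$Z) - t(model$Y)[model$centroid, , drop = FALSE])^2))
  model$center <- center
  model$centroid_pseudotime <- dcen
  model$pseudotime_global <- dcen[model$centroid] + offset

  pt_branch <- numeric(ncol(model$Z))
  for (b in unique(model$centroid_branch)) {
    nodes <- which(model$centroid_branch == b)
    origin <- nodes[which.min(dcen[nodes])]
    dor <- as.numeric(igraph::distances(g, v = as.character(origin)))
    sel <- model$branch_id == b
    pt_branch[sel] <- dor[model$centroid[sel]] + offset[sel]
  }
  model$pseudotime_branch <- pt_branch
  model
}

#' Per-sample tree table
#'
#' @param model a fitted tree, ideally after [merge_branches()] and
#'   [compute_pseudotime()].
#' @param ids optional sample identifiers.
#' @return tibble: id, dim1, dim2, centroid, branch, phenogroup,
#'   pseudotime_global, pseudotime_branch.
#' @export
tree_samples <- function(model, ids = NULL) {
  stopifnot(inherits(model, "tree_model"))
  n <- ncol(model$Z)
  tibble::tibble(
    id = ids %||% rownames(model$X) %||% sprintf("s%05d", seq_len(n)),
    dim1 = model$Z[1, ], dim2 = model$Z[2, ],
    centroid = model$centroid,
    branch = model$branch_id %||% rep(NA_integer_, n),
    phenogroup = model$phenogroup %||% rep(NA_integer_, n),
    pseudotime_global = model$pseudotime_global %||% rep(NA_real_, n),
    pseudotime_branch = model$pseudotime_branch %||% rep(NA_real_, n))
}

#' Bootstrap stability of the phenogroup partition
#'
#' Refits the tree on bootstrap resamples and scores, on the unique samples
#' appearing in each resample, the adjusted Rand index between the
#' reference phenogroup labels and the resample's labels.
#'
#' @param X samples x features matrix.
#' @param params [ddrtree_params()].
#' @param n_groups phenogroups for merging.
#' @param n_boot number of bootstrap resamples (>= 2).
#' @param seed RNG seed.
#' @param standardize passed to [fit_ddrtree()].
#' @return list with `median`, `iqr`, `ari` (per-resample values) and the
#'   reference model.
#' @export
stability_ari <- function(X, params = ddrtree_params(), n_groups = 6,
                          n_boot = 10, seed = 1, standardize = TRUE) {
  if (n_boot < 2) stopf("n_boot must be >= 2")
  X <- as.matrix(X)
  ref <- merge_branches(assign_branches(
    fit_ddrtree(X, params, seed = seed, standardize = standardize)),
    n_groups = n_groups)
  aris <- with_seed(seed + 1L, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(X), replace = TRUE)
      fit <- suppressWarnings(
        merge_branches(assign_branches(
          fit_ddrtree(X[idx, , drop = FALSE], params, seed = seed + b,
                      standardize = standardize)),
          n_groups = n_groups))
      first <- !duplicated(idx)
      adjusted_rand_index(ref$phenogroup[idx[first]], fit$phenogroup[first])
    }, numeric(1))
  })
  list(median = median(aris), iqr = unname(quantile(aris, 0.75) - quantile(aris, 0.25)),
       ari = aris, reference = ref)
}
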