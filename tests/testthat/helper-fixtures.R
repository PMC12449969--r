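# Shared fixtures, generated in code. Expensive ones are cached for the
# duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 3-armed star along orthogonal directions in 10-D
make_star <- function(n_per = 200, noise = 0.05, seed = 1, n_dim = 10) {
  set.seed(seed)
  dirs <- diag(n_dim)[1:3, , drop = FALSE]
  arm <- rep(1:3, each = n_per)
  tt <- runif(3 * n_per)
  X <- tt * dirs[arm, , drop = FALSE] +
    matrix(rnorm(3 * n_per * n_dim, 0, noise), ncol = n_dim)
  list(X = X, arm = arm)
}

fit_star_tree <- function(n_per = 200, noise = 0.05, seed = 1, K = 60, n_groups = 3) {
  s <- make_star(n_per, noise, seed)
  fit <- suppressWarnings(fit_ddrtree(s$X, ddrtree_params(K = K), seed = seed,
                                      standardize = FALSE))
  fit <- compute_pseudotime(merge_branches(assign_branches(fit), n_groups = n_groups))
  list(fit = fit, star = s)
}

# small cohort of median beats shared across VAE tests
small_beat_cohort <- function() {
  cached("small_beat_cohort", generate_cohort(220, seed = 41, waveforms = "median"))
}

# a tiny trained VAE shared across tests that only need a working model
small_vae <- function() {
  cached("small_vae", {
    co <- small_beat_cohort()
    train_vae(co$records[1:160],
              vae_config(latent_dim = 8, n_blocks = 4, epochs = 6,
                         batch_size = 32, seed = 7))
  })
}

# hand-built path-shaped tree model: K nodes at unit spacing on a line,
# one sample sitting on each node
path_tree_model <- function(K = 7) {
  Y <- rbind(seq_len(K) - (K + 1) / 2, rep(0, K))
  B <- matrix(0, K, K)
  for (j in seq_len(K - 1)) B[j, j + 1] <- B[j + 1, j] <- 1
  R <- diag(K)
  structure(list(X = t(Y), W = diag(2), Z = Y, Y = Y, B = B, R = R,
                 centroid = seq_len(K),
                 hyperparams = list(K = K, sigma = 1e-3, gamma = 10),
                 objective = 0, converged = TRUE,
                 branch_id = NULL, phenogroup = NULL,
                 pseudotime_global = NULL, pseudotime_branch = NULL),
            class = "tree_model")
}

# chance-corrected partition agreement, resolvable in any load mode
adjusted_rand_index <- function(a, b) mclust::adjustedRandIndex(a, b)

# independent MST oracle (igraph) on 2 x K node coordinates
mst_oracle_adjacency <- function(Y) {
  D <- as.matrix(dist(t(Y)))
  g <- igraph::graph_from_adjacency_matrix(D, weighted = TRUE, mode = "undirected")
  unname(as.matrix(igraph::as_adjacency_matrix(igraph::mst(g))) * 1)
}

# brute-force nearest-point-on-segment oracle for snapping tests
snap_oracle <- function(p, Y, edges) {
  best <- Inf
  best_pt <- c(NA, NA)
  for (e in seq_len(nrow(edges))) {
    a <- Y[, edges[e, 1]]
    b <- Y[, edges[e, 2]]
    for (tt in seq(0, 1, length.out = 2001)) {
      q <- a + tt * (b - a)
      d <- sum((p - q)^2)
      if (d < best) { best <- d; best_pt <- q }
    }
  }
  list(pt = best_pt, dist = sqrt(best))
}

expect_tree_invariants <- function(model) {
  K <- nrow(model$B)
  expect_true(isSymmetric(model$B))
  expect_equal(sum(model$B) / 2, K - 1)
  g <- igraph::graph_from_adjacency_matrix(model$B != 0, mode = "undirected")
  expect_equal(igraph::components(g)$no, 1L)
  expect_true(igraph::is_acyclic(g))
  expect_equal(rowSums(model$R), rep(1, ncol(model$Z)), tolerance = 1e-8)
  expect_equal(crossprod(model$W), diag(ncol(model$W)), tolerance = 1e-6,
               ignore_attr = TRUE)
  dif <- diff(model$objective)
  expect_true(all(dif <= 1e-9 * pmax(1, abs(model$objective[-length(model$objective)]))))
}
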