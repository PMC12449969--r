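# DDRTree core: structural invariants, geometry recovery, branches,
# merging, pseudotime and stability.

test_that("default hyperparameters use 2000 centroids and standard values", {
  p <- ddrtree_params()
  expect_equal(p$K, 2000L)
  expect_equal(p$sigma, 1e-3)
  expect_equal(p$gamma, 10)
})

test_that("collinear data yields a path with a monotone objective", {
  set.seed(1)
  t <- seq(0, 1, length.out = 50)
  X <- outer(t, rnorm(10))
  f <- suppressWarnings(fit_ddrtree(X, ddrtree_params(K = 10, max_iter = 30),
                                    standardize = FALSE))
  expect_tree_invariants(f)
  deg <- colSums(f$B)
  expect_equal(sum(deg == 1), 2)             # exactly two leaves: a path
  expect_lte(tail(f$objective, 1), f$objective[1])

  f <- assign_branches(f)
  expect_equal(max(f$branch_edges[, "branch"]), 1)   # single sub-branch
})

test_that("with K = N and a cold assignment the backbone is the exact MST", {
  set.seed(4)
  X <- matrix(rnorm(12 * 5), 12, 5)
  f <- suppressWarnings(fit_ddrtree(X, ddrtree_params(K = 12, sigma = 1e-6,
                                                      max_iter = 10)))
  expect_tree_invariants(f)
  # Kruskal-style oracle via igraph on the complete weighted graph over
  # the embedded centroids
  D <- as.matrix(dist(t(f$Y)))
  g <- igraph::graph_from_adjacency_matrix(D, weighted = TRUE,
                                           mode = "undirected")
  mst <- igraph::mst(g, algorithm = "prim")
  oracle <- as.matrix(igraph::as_adjacency_matrix(mst)) != 0
  expect_equal(unname(f$B != 0), unname(oracle))
})

test_that("three-armed star is recovered as three phenogroups", {
  aris <- vapply(1:10, function(sd) {
    st <- fit_star_tree(seed = sd)
    adjusted_rand_index(st$fit$phenogroup, st$star$arm)
  }, numeric(1))
  expect_gte(median(aris), 0.8)
})

test_that("sub-branch decomposition matches the terminal-count oracle", {
  # on any tree, sub-branches = #(nodes with degree != 2) - 1
  set.seed(7)
  for (rep in 1:8) {
    K <- sample(4:20, 1)
    Y <- rbind(runif(K), runif(K))
    B <- mst_oracle_adjacency(Y)
    model <- structure(list(X = t(Y), W = diag(2), Z = Y, Y = Y, B = B,
                            R = diag(K), centroid = seq_len(K),
                            objective = 0, converged = TRUE),
                       class = "tree_model")
    model <- assign_branches(model)
    deg <- colSums(B)
    expect_equal(max(model$branch_edges[, "branch"]), sum(deg != 2) - 1)
    # every edge belongs to exactly one sub-branch
    expect_false(anyNA(model$branch_edges[, "branch"]))
  }
})

test_that("merging respects identity cuts, bounds and contiguity", {
  st <- fit_star_tree(seed = 2)
  fit <- st$fit
  nb <- max(fit$branch_edges[, "branch"])
  same <- merge_branches(fit, n_groups = nb)
  expect_equal(adjusted_rand_index(same$centroid_branch, same$centroid_phenogroup), 1)
  expect_error(merge_branches(fit, n_groups = nb + 1), "exceeds")
  expect_equal(ddrtree_params()$K, 2000L)

  merged <- merge_branches(fit, n_groups = 3)
  # contiguity: each phenogroup's centroids induce a connected subtree
  g <- igraph::graph_from_adjacency_matrix(merged$B != 0, mode = "undirected")
  for (ph in unique(merged$centroid_phenogroup)) {
    sub <- igraph::induced_subgraph(g, which(merged$centroid_phenogroup == ph))
    expect_equal(igraph::components(sub)$no, 1L)
  }
})

test_that("the two spatially closest sub-branches merge first", {
  # hand-built 4-arm cross: arms at 0, 30, 180 and 270 degrees around a
  # hub; the 0/30-degree pair has by far the closest means and must share
  # a label after one merge
  ang <- c(0, 30, 180, 270) * pi / 180
  Y <- matrix(0, 2, 9)
  B <- matrix(0, 9, 9)
  for (a in seq_along(ang)) {
    n1 <- 2 * a; n2 <- 2 * a + 1
    Y[, n1] <- c(cos(ang[a]), sin(ang[a]))
    Y[, n2] <- 2 * c(cos(ang[a]), sin(ang[a]))
    B[1, n1] <- B[n1, 1] <- 1
    B[n1, n2] <- B[n2, n1] <- 1
  }
  model <- structure(list(X = t(Y), W = diag(2), Z = Y, Y = Y, B = B,
                          R = diag(9), centroid = 1:9,
                          objective = 0, converged = TRUE),
                     class = "tree_model")
  model <- assign_branches(model)
  expect_equal(max(model$branch_edges[, "branch"]), 4)
  m1 <- merge_branches(model, n_groups = 3)
  expect_equal(length(unique(m1$centroid_phenogroup)), 3)
  lab_of_tip <- function(node) m1$centroid_phenogroup[node]
  expect_equal(lab_of_tip(3), lab_of_tip(5))     # 0 and 30 degree arms fused
  expect_false(lab_of_tip(7) == lab_of_tip(9))   # far arms stay apart
})

test_that("pseudotime equals geodesic distance on a hand-built path", {
  model <- path_tree_model(K = 7)
  model <- compute_pseudotime(assign_branches(model))
  center <- model$center
  # Dijkstra oracle on unit-spaced path nodes
  expect_equal(model$centroid_pseudotime, abs(seq_len(7) - center))
  expect_equal(model$pseudotime_global, abs(seq_len(7) - center))
  expect_equal(model$pseudotime_global[center], 0)
  # monotone non-decreasing away from the branch origin
  left <- rev(model$pseudotime_branch[seq_len(center)])
  right <- model$pseudotime_branch[center:7]
  expect_true(all(diff(left) >= 0) || all(diff(right) >= 0))
  expect_true(all(model$pseudotime_branch >= 0))
})

test_that("samples at the tree center have near-zero pseudotime", {
  st <- fit_star_tree(seed = 5)
  fit <- st$fit
  offs <- sqrt(colSums((fit$Z - fit$Y[, fit$centroid])^2))
  at_center <- which(fit$centroid == fit$center)
  expect_true(length(at_center) > 0)
  expect_equal(fit$pseudotime_global[at_center], offs[at_center])
})

test_that("phenogroup partition is invariant to feature-space rotation", {
  s <- make_star(n_per = 40, seed = 9)
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(100), 10)))
  f1 <- suppressWarnings(merge_branches(assign_branches(
    fit_ddrtree(s$X, ddrtree_params(K = 20), seed = 1, standardize = FALSE)), 3))
  f2 <- suppressWarnings(merge_branches(assign_branches(
    fit_ddrtree(s$X %*% Q, ddrtree_params(K = 20), seed = 1, standardize = FALSE)), 3))
  expect_equal(adjusted_rand_index(f1$phenogroup, f2$phenogroup), 1)
})

test_that("bootstrap stability behaves at its anchors", {
  expect_equal(adjusted_rand_index(rep(1:3, 10), rep(1:3, 10)), 1)
  # random labels have ARI about zero
  set.seed(11)
  ref <- sample(1:6, 500, replace = TRUE)
  null_ari <- mean(vapply(1:50, function(i)
    adjusted_rand_index(ref, sample(ref)), numeric(1)))
  expect_lt(abs(null_ari), 0.05)

  s <- make_star(n_per = 80, noise = 0.03, seed = 2)
  sa <- suppressWarnings(stability_ari(s$X, ddrtree_params(K = 30), n_groups = 3,
                                       n_boot = 10, seed = 3,
                                       standardize = FALSE))
  expect_gte(sa$median, 0.8)
  expect_length(sa$ari, 10)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_ddrtree(matrix(1:4, 2, 2)), "at least 3")
  expect_error(fit_ddrtree(matrix(rnorm(30), 10, 3), ddrtree_params(K = 1)), "K must be")
  X <- matrix(rnorm(30), 10, 3)
  X[1, 1] <- NA
  expect_error(fit_ddrtree(X), "non-finite")
  expect_warning(fit_ddrtree(matrix(rnorm(50), 10, 5), ddrtree_params(K = 50)),
                 "clamping")
})
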