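test_that("weighted density evaluates the max-normalized mean weight", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.1
  expect_equal(weighted_density(w), (1 + 0.5 + 0) / 3)
  # uniform positive weights saturate at 1
  u <- matrix(0.7, 4, 4); diag(u) <- 0
  expect_equal(weighted_density(u), 1)
  expect_equal(weighted_density(matrix(0, 5, 5)), 0)
})

test_that("density-matched binarization keeps the k largest edges", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.1
  b <- binarize_to_density(w, 1 / 3)
  expect_equal(sum(b$adjacency) / 2, 1)
  expect_equal(b$adjacency[1, 2], 1)
  expect_equal(binarize_to_density(w, 1)$adjacency, (w > 0) * 1)
  expect_equal(sum(binarize_to_density(w, 0)$adjacency), 0)
  # zero-weight pairs never become edges even when k demands it
  sparse <- matrix(0, 4, 4); sparse[1, 2] <- sparse[2, 1] <- 1
  expect_equal(sum(binarize_to_density(sparse, 1)$adjacency) / 2, 1)
  # achieved density within one-edge resolution of the target
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    w <- random_connectome(n, density = 1, seed = i)  # distinct weights
    target <- runif(1)
    b <- binarize_to_density(w, target)
    m <- n * (n - 1) / 2
    expect_lte(abs(sum(b$adjacency) / 2 / m - target), 1 / m + 1e-12)
  }
})

test_that("binary suite matches closed forms on canonical graphs", {
  k3 <- adj_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
  v <- binary_measure_suite(k3)
  expect_equal(v[["density"]], 1)
  expect_equal(v[["transitivity"]], 1)
  expect_equal(v[["clustering_mean"]], 1)
  expect_equal(v[["betweenness_mean"]], 0)
  path3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  v <- binary_measure_suite(path3)
  expect_equal(v[["density"]], 2 / 3)
  expect_equal(v[["transitivity"]], 0)
  expect_equal(v[["betweenness_mean"]], 1 / 3)  # only the middle node: 1
  expect_equal(v[["betweenness_median"]], 0)
  # star: centre flow coefficient 1 (no leaf pair directly connected),
  # leaves 0 (degree 1)
  star <- adj_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  v <- binary_measure_suite(star)
  expect_equal(v[["flow_mean"]], 1 / 5)
  # empty graph conventions
  v0 <- binary_measure_suite(matrix(0, 4, 4))
  expect_true(all(v0 == 0))
})

test_that("weighted suite matches closed forms", {
  # complete K4 with equal weights: lambda2(L) = 4w, efficiency 1
  w <- matrix(0.25, 4, 4); diag(w) <- 0
  v <- weighted_measure_suite(w)
  expect_equal(v[["algebraic_connectivity"]], 4 * 0.25, tolerance = 1e-9)
  expect_equal(v[["global_efficiency_w"]], 1)
  # two disconnected components have zero algebraic connectivity
  w2 <- matrix(0, 4, 4)
  w2[1, 2] <- w2[2, 1] <- 1
  w2[3, 4] <- w2[4, 3] <- 1
  expect_equal(weighted_measure_suite(w2)[["algebraic_connectivity"]], 0,
               tolerance = 1e-9)
  # participation: strength split 50/50 across two modules -> 0.5
  memb <- c(1, 1, 2, 2)
  wp <- matrix(0, 4, 4)
  wp[1, 2] <- wp[2, 1] <- 1   # node 1 inside module 1
  wp[1, 3] <- wp[3, 1] <- 1   # node 1 into module 2
  s1 <- 2
  p1 <- 1 - sum((rowsum(wp[1, ], memb) / s1)^2)
  expect_equal(p1, 0.5)
  # node with all edges in its own module has participation 0
  expect_equal(1 - sum((rowsum(wp[2, ], memb) / 1)^2), 0)
})

test_that("quasi-idempotence is the strength correlation of W and W^2", {
  w <- random_connectome(6, density = 0.8, seed = 2)
  wn <- w / max(w)
  expected <- cor(rowSums(wn), rowSums(wn %*% wn))
  expect_equal(weighted_measure_suite(w)[["quasi_idempotence"]], expected)
  # constant strengths -> undefined, reported missing
  ring <- adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  expect_true(is.na(weighted_measure_suite(ring)[["quasi_idempotence"]]))
})

test_that("eigenvector centrality satisfies the eigen equation", {
  set.seed(7)
  for (i in 1:10) {
    w <- random_connectome(6, density = 0.9, seed = i)
    v <- strokenet:::principal_eigenvector(w)
    lam <- max(eigen(w, symmetric = TRUE, only.values = TRUE)$values)
    expect_lt(max(abs(w %*% v - lam * v)), 1e-8)
    expect_true(all(v >= 0))
    expect_equal(sum(v^2), 1)
  }
})

test_that("measures are invariant under node permutation and weight scaling", {
  w <- random_connectome(8, density = 0.6, seed = 3)
  # plant clear two-module structure so the Louvain partition is stable
  w[1:4, 1:4] <- w[1:4, 1:4] + 2
  w[5:8, 5:8] <- w[5:8, 5:8] + 2
  diag(w) <- 0
  base <- connectome_measures(w)
  perm <- c(3, 1, 4, 2, 8, 5, 7, 6)
  expect_equal(connectome_measures(w[perm, perm]), base, tolerance = 1e-8)
  scaled <- connectome_measures(5 * w)
  scale_free <- setdiff(measure_names(), "algebraic_connectivity")
  expect_equal(scaled[scale_free], base[scale_free], tolerance = 1e-8)
  expect_equal(scaled[["algebraic_connectivity"]],
               5 * base[["algebraic_connectivity"]], tolerance = 1e-8)
})

test_that("patient averaging is the pairwise-complete mean", {
  v1 <- c(density = 0, quasi_idempotence = NA_real_)
  v2 <- c(density = 1, quasi_idempotence = 0.5)
  v3 <- c(density = 0.5, quasi_idempotence = 0.7)
  avg <- patient_measure_average(list(v1, v2, v3))
  expect_equal(unname(avg["density"]), 0.5)
  expect_equal(unname(avg["quasi_idempotence"]), 0.6)
  expect_equal(unname(attr(avg, "n_used")["quasi_idempotence"]), 2)
  same <- patient_measure_average(list(v2, v2, v2))
  expect_equal(unname(same["density"]), 1)
  expect_error(patient_measure_average(list()), "empty")
})
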