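test_that("vibrational centrality matches hand pseudoinverses", {
  fx <- fixture_graphs()
  expect_equal(unname(vibrational_centrality(fx$p2)), c(0.5, 0.5))
  expect_equal(unname(vibrational_centrality(fx$k3)), rep(sqrt(2 / 9), 3))
  # vertex-transitive graph (5-cycle): all displacements equal
  c5 <- springgeo:::new_gene_network(paste0("v", 1:5), cbind(1:5, c(2:5, 1)))
  dx <- vibrational_centrality(c5)
  expect_lt(diff(range(dx)), 1e-12)
  # temperature scaling: delta_x ~ sqrt(T / k0)
  expect_equal(unname(vibrational_centrality(fx$p2, temperature = 4)),
               c(1, 1))
})

test_that("weighted incidence row-scales by mass; kernel direction invariant", {
  fx <- fixture_graphs()
  A <- oriented_incidence(fx$star3)
  m <- node_masses(fx$star3)
  C <- weighted_incidence(A, m)
  expect_equal(unname(C["hub", ]), c(3, 3, 3))
  expect_equal(unname(C["l1", 1]), -1)
  expect_equal(colSums(C != 0), rep(2, 3))
  # scaling all masses by c scales C and preserves the nullspace of t(C)
  K1 <- stiffness_equilibrium(C)
  K2 <- stiffness_equilibrium(weighted_incidence(A, 2 * m))
  expect_equal(K1$K, K2$K, tolerance = 1e-12)
  expect_error(weighted_incidence(A, c(0, 1, 1, 1)), "zero")
})

test_that("equilibrium stiffness reproduces the closed forms", {
  fx <- fixture_graphs()
  Kp2 <- stiffness_equilibrium(
    weighted_incidence(oriented_incidence(fx$p2), node_masses(fx$p2)))
  expect_equal(unname(Kp2$K), matrix(0.5, 2, 2), tolerance = 1e-12)
  Kk3 <- stiffness_equilibrium(
    weighted_incidence(oriented_incidence(fx$k3), node_masses(fx$k3)))
  expect_equal(unname(Kk3$K), matrix(1 / 3, 3, 3), tolerance = 1e-12)
  Kst <- stiffness_equilibrium(
    weighted_incidence(oriented_incidence(fx$star3), node_masses(fx$star3)))
  expect_equal(Kst$K["hub", "l1"], 3 / 28, tolerance = 1e-12)
  expect_equal(Kst$K["l1", "l2"], 9 / 28, tolerance = 1e-12)
  expect_equal(Kst$kernel_dim, 1L)
})

test_that("kernel certificate and closed-form oracle hold on random graphs", {
  for (s in 1:25) {
    g <- rand_connected_graph(sample(4:30, 1), seed = 500 + s)
    m <- node_masses(g)
    C <- weighted_incidence(oriented_incidence(g), m)
    K <- stiffness_equilibrium(C)
    # certificate: m_i v_i = m_j v_j on every edge, for every basis vector
    N <- K$kernel_basis
    res <- abs(m[g$edges[, 1]] * N[g$edges[, 1], , drop = FALSE] -
                 m[g$edges[, 2]] * N[g$edges[, 2], , drop = FALSE])
    expect_lt(max(res), 1e-10 * max(m))
    # closed form for a connected graph
    v <- 1 / m
    expect_equal(unname(K$K), unname(outer(v, v) / sum(v^2)),
                 tolerance = 1e-12)
    expect_equal(K$kernel_dim, 1L)
  }
})

test_that("stiffness is orientation invariant, PSD, block-diagonal per component", {
  g <- rand_connected_graph(12, seed = 9)
  m <- node_masses(g)
  A <- oriented_incidence(g)
  K1 <- stiffness_equilibrium(weighted_incidence(A, m))
  set.seed(2)
  flip <- sample(c(-1, 1), ncol(A), replace = TRUE)
  K2 <- stiffness_equilibrium(weighted_incidence(A %*% diag(flip), m))
  expect_equal(K1$K, K2$K, tolerance = 1e-12)
  # PSD with trace = kernel_dim
  ev <- eigen(K1$K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
  expect_equal(sum(diag(K1$K)), K1$kernel_dim, tolerance = 1e-10)

  fx <- fixture_graphs()
  gd <- fx$cliques10_disjoint
  Kd <- stiffness_equilibrium(
    weighted_incidence(oriented_incidence(gd), node_masses(gd)))
  expect_equal(Kd$kernel_dim, 2L)
  expect_equal(unname(Kd$K[1:10, 11:20]), matrix(0, 10, 10),
               tolerance = 1e-12)
  expect_equal(unname(Kd$K), unname(attr(gd, "expected")$stiffness),
               tolerance = 1e-12)
})

test_that("non-equilibrium stiffness: zero forces, invertibility, LS oracle", {
  fx <- fixture_graphs()
  A <- oriented_incidence(fx$p2)
  C <- weighted_incidence(A, node_masses(fx$p2))
  expect_warning(K0 <- stiffness_nonequilibrium(C, c(0, 0), c(1, 1)),
                 "pseudoinverse")
  expect_equal(unname(K0$K), matrix(0, 2, 2))
  expect_error(stiffness_nonequilibrium(C, c(1, -1), c(1, 0)), "non-zero")
  # single edge: minimal-norm least-squares oracle via an independent ginv
  K <- suppressWarnings(stiffness_nonequilibrium(C, c(1, -1), c(1, 1)))
  Fedge <- matrix(c(1, -1), 1, 2)  # forces restricted to the edge's endpoints
  oracle <- MASS::ginv(t(C)) %*% Fedge %*% diag(2)
  oracle <- (oracle + t(oracle)) / 2
  expect_equal(unname(K$K), oracle, tolerance = 1e-10)
})

test_that("rescaling maps stiffness to [0,1] and is scale invariant", {
  fx <- fixture_graphs()
  Kst <- stiffness_equilibrium(
    weighted_incidence(oriented_incidence(fx$star3), node_masses(fx$star3)))
  R <- rescale_stiffness(Kst)
  expect_equal(R$K_rescaled["hub", "l1"], 0)
  expect_equal(R$K_rescaled["l1", "l2"], 1)
  # invariant to positive scaling of K
  K10 <- Kst; K10$K <- 10 * Kst$K
  expect_equal(rescale_stiffness(K10)$K_rescaled[upper.tri(R$K_rescaled)],
               R$K_rescaled[upper.tri(R$K_rescaled)], tolerance = 1e-12)
  # degenerate: triangle has all off-diagonal stiffness equal
  Kk3 <- stiffness_equilibrium(
    weighted_incidence(oriented_incidence(fx$k3), node_masses(fx$k3)))
  expect_warning(Rk3 <- rescale_stiffness(Kk3), "degenerate")
  expect_equal(unname(Rk3$K_rescaled[upper.tri(Rk3$K_rescaled)]), rep(1, 3))
})

test_that("dissimilarity is 1/(1 + k) with forced zero diagonal", {
  fx <- fixture_graphs()
  Kst <- rescale_stiffness(stiffness_equilibrium(
    weighted_incidence(oriented_incidence(fx$star3), node_masses(fx$star3))))
  D <- stiffness_to_dissimilarity(Kst)
  expect_equal(D["hub", "l1"], 1)    # rescaled stiffness 0
  expect_equal(D["l1", "l2"], 0.5)   # rescaled stiffness 1
  expect_equal(diag(D), setNames(rep(0, 4), rownames(D)))
  off <- D[upper.tri(D)]
  expect_true(all(off >= 0.5 & off <= 1))
  # monotonicity: larger rescaled stiffness, smaller dissimilarity
  M <- Kst$K_rescaled
  ut <- upper.tri(M)
  ord <- order(M[ut])
  expect_true(all(diff(D[ut][ord]) <= 1e-15))
})

test_that("matrix CSV round-trips with node-id header", {
  fx <- fixture_graphs()
  D <- stiffness_to_dissimilarity(rescale_stiffness(stiffness_equilibrium(
    weighted_incidence(oriented_incidence(fx$star3), node_masses(fx$star3)))))
  path <- tempfile(fileext = ".csv")
  write_matrix_csv(D, path)
  back <- read_matrix_csv(path)
  expect_equal(back, D, tolerance = 1e-12)
})
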