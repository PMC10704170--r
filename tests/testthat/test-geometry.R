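test_that("metric distances match closed forms in all three models", {
  eu <- metric_model("euclidean")
  expect_equal(metric_distance(c(0, 0), c(3, 4), eu), 5)
  hy <- metric_model("hyperbolic")
  expect_equal(metric_distance(c(0, 0), c(0, 0), hy), 0)
  a <- c(0.3, -0.2); b <- c(-0.1, 0.55)
  expect_equal(metric_distance(a, b, hy), metric_distance(b, a, hy))
  expect_equal(metric_distance(c(0, 0), c(0.5, 0), hy), log(3))
  expect_error(metric_distance(c(1, 0), c(0, 0), hy), "unit ball")
  sp <- metric_model("spherical", radius = 2)
  expect_equal(metric_distance(c(2, 0, 0), c(0, 2, 0), sp), pi)
  expect_error(metric_distance(c(1, 0, 0), c(0, 2, 0), sp), "sphere")
})

test_that("complex disk formula and acosh ball formula agree", {
  set.seed(101)
  n <- 1000
  r <- sqrt(runif(n)) * 0.97; th <- runif(n, 0, 2 * pi)
  z1 <- complex(modulus = r, argument = th)
  r2 <- sqrt(runif(n)) * 0.97; th2 <- runif(n, 0, 2 * pi)
  z2 <- complex(modulus = r2, argument = th2)
  hy <- metric_model("hyperbolic")
  for (i in seq_len(n)) {
    d_complex <- poincare_distance_complex(z1[i], z2[i])
    d_ball <- metric_distance(c(Re(z1[i]), Im(z1[i])),
                              c(Re(z2[i]), Im(z2[i])), hy)
    expect_equal(d_ball, d_complex, tolerance = 1e-12)
  }
  # small-argument limit d(0, z) -> 2|z|
  expect_equal(metric_distance(c(0, 0), c(1e-3, 0), hy) / 2e-3, 1,
               tolerance = 1e-4)
})

test_that("classical MDS recovers exact Euclidean configurations", {
  X <- rbind(c(0, 0), c(3, 0), c(0, 4))
  D <- as.matrix(dist(X)); dimnames(D) <- list(letters[1:3], letters[1:3])
  emb <- embed_euclidean(D, 2)
  expect_lt(emb$stress, 1e-10)
  Demb <- as.matrix(dist(emb$coordinates))
  expect_equal(unname(Demb), unname(D), tolerance = 1e-9)
  expect_error(embed_euclidean(D, 3), "p must be <")

  # higher-dimensional planted points, recovered to 1e-9 when p >= p_true
  set.seed(7)
  Y <- matrix(rnorm(20 * 3), 20, 3)
  DY <- as.matrix(dist(Y)); dimnames(DY) <- list(NULL, NULL)
  e2 <- embed_euclidean(DY, 4)
  expect_equal(as.matrix(dist(e2$coordinates)), DY, tolerance = 1e-9,
               ignore_attr = TRUE)

  # stress of an exactly Euclidean D is invariant to permutations
  set.seed(8)
  perm <- sample(nrow(DY))
  e3 <- embed_euclidean(DY[perm, perm], 4)
  expect_equal(e3$stress, e2$stress, tolerance = 1e-8)
})

test_that("hyperbolic embedding is exact for two points and accurate for planted disks", {
  for (d in c(0.2, 1, 2.3, 5)) {
    D <- matrix(c(0, d, d, 0), 2)
    emb <- suppressWarnings(embed_hyperbolic(D, 2))
    got <- metric_distance(emb$coordinates[1, ], emb$coordinates[2, ],
                           emb$model)
    expect_equal(got, d, tolerance = 1e-6)
  }
  cfg <- sample_points("hyperbolic", 50, 2, list(R = 3), seed = 17)
  D <- planted_dissimilarity(cfg)
  emb <- embed_hyperbolic(D, 2)
  expect_true(all(sqrt(rowSums(emb$coordinates^2)) < 1))
  Demb <- springgeo:::pairwise_model_distances(emb$coordinates, emb$model)
  ut <- upper.tri(D)
  rel <- abs(Demb[ut] - D[ut]) / D[ut]
  expect_lte(median(rel), 0.05)
})

test_that("hyperbolic curvature parameter rescales the model consistently", {
  # distances under kappa are 1/sqrt(kappa) times the unit-curvature value
  u <- c(0.3, 0.1); v <- c(-0.2, 0.4)
  expect_equal(metric_distance(u, v, metric_model("hyperbolic", curvature = 4)),
               metric_distance(u, v, metric_model("hyperbolic")) / 2)
  # equivariance: embedding D at curvature kappa is the same problem as
  # embedding sqrt(kappa) D at curvature 1, with stress scaled by 1/kappa
  cfg <- sample_points("hyperbolic", 25, 2, list(R = 2), seed = 23)
  D <- planted_dissimilarity(cfg)
  e4 <- embed_hyperbolic(D, 2, kappa = 4)
  e1 <- embed_hyperbolic(2 * D, 2, kappa = 1)
  expect_equal(e4$stress, e1$stress / 4, tolerance = 1e-8)
  expect_equal(e4$coordinates, e1$coordinates, tolerance = 1e-6)
})

test_that("spherical embedding recovers the planted radius and sphere", {
  cfg <- sample_points("spherical", 20, 2, list(radius = 1), seed = 3)
  D <- planted_dissimilarity(cfg)
  emb <- embed_spherical(D, 3)
  expect_equal(emb$details$r_star, 1, tolerance = 0.01)
  expect_lt(emb$stress, 1e-4)
  nrm <- sqrt(rowSums(emb$coordinates^2))
  expect_lt(max(abs(nrm - emb$details$r_star)), 1e-8)
  # scale equivariance: distances scaled by c give radius c * r_star
  emb2 <- embed_spherical(2.5 * D, 3)
  expect_equal(emb2$details$r_star, 2.5 * emb$details$r_star,
               tolerance = 0.01)
})

test_that("embedding stress is the pairwise residual sum of squares", {
  D <- matrix(c(0, 1, 1, 0), 2)
  emb <- springgeo:::new_embedding(rbind(c(0, 0), c(2, 0)),
                                   metric_model("euclidean"), 2, NA)
  expect_equal(as.numeric(embedding_stress(D, emb)), 1)
  # perfect embedding: zero stress
  X <- rbind(c(0, 0), c(1, 0), c(0.3, 0.8))
  DX <- as.matrix(dist(X))
  embX <- springgeo:::new_embedding(X, metric_model("euclidean"), 2, NA)
  expect_equal(as.numeric(embedding_stress(DX, embX)), 0)
  # invariance under rotations of the model space
  th <- 0.83; R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  cfg <- sample_points("hyperbolic", 15, 2, list(R = 2), seed = 5)
  D15 <- planted_dissimilarity(cfg)
  e0 <- springgeo:::new_embedding(cfg$coords, metric_model("hyperbolic"), 2, NA)
  e1 <- springgeo:::new_embedding(cfg$coords %*% R,
                                  metric_model("hyperbolic"), 2, NA)
  expect_equal(as.numeric(embedding_stress(D15, e1)),
               as.numeric(embedding_stress(D15, e0)), tolerance = 1e-10)
  expect_error(embedding_stress(D15[1:10, 1:10], e0), "mismatch")
})

test_that("select_geometry picks the planted model and survives failures", {
  for (model in c("euclidean", "hyperbolic", "spherical")) {
    cfg <- sample_points(model, 40, 2, seed = 77)
    D <- planted_dissimilarity(cfg)
    tab <- suppressWarnings(select_geometry(D, dims = 3))
    expect_equal(attr(tab, "best_model"), model)
    expect_equal(min(tab$stress), tab$stress[which.min(tab$stress)])
  }
  # a failing dimension is dropped with a warning, not an abort
  cfg <- sample_points("euclidean", 5, 2, seed = 1)
  D <- planted_dissimilarity(cfg)
  expect_warning(tab <- select_geometry(D, dims = c(3, 10), models = "euclidean"),
                 "failed")
  expect_equal(nrow(tab), 1L)
})
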