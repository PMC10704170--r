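# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# exhaustive/dynamic-programming optimal 1-D k-means (minimal WSS)
dp_kmeans_wss <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  seg_cost <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k, n)
  for (j in 1:n) dp[1, j] <- seg_cost(1, j)
  if (k > 1) for (kk in 2:k) for (j in kk:n) {
    for (i in kk:j) {
      cand <- dp[kk - 1, i - 1] + seg_cost(i, j)
      if (cand < dp[kk, j]) dp[kk, j] <- cand
    }
  }
  dp[k, n]
}

# adjusted Rand index between two label vectors
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# random connected graph: random spanning tree + extra random edges
rand_connected_graph <- function(n, extra = n, seed = 1L) {
  set.seed(seed)
  edges <- cbind(vapply(2:n, function(t) sample.int(t - 1L, 1L), 0L), 2:n)
  if (n >= 3 && extra > 0) {
    more <- cbind(sample.int(n, extra, replace = TRUE),
                  sample.int(n, extra, replace = TRUE))
    more <- more[more[, 1] != more[, 2], , drop = FALSE]
    edges <- rbind(edges, t(apply(more, 1, sort)))
  }
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  springgeo:::new_gene_network(sprintf("v%03d", seq_len(n)), edges)
}

# random possibly-disconnected graph (Bernoulli edges)
rand_graph <- function(n, p = 0.15, seed = 1L) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  if (nrow(edges) == 0L) edges <- pairs[1, , drop = FALSE]
  springgeo:::new_gene_network(sprintf("v%03d", seq_len(n)), edges)
}

# union-find component count, independent of the package's BFS
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

# write a SIF file from triples
write_sif_lines <- function(lines) {
  path <- tempfile(fileext = ".sif")
  writeLines(lines, path)
  path
}

# two-component mixture used by the driver-recovery simulations
rmixture <- function(n, w = 0.5) {
  comp <- runif(n) < w
  v <- ifelse(comp, rnorm(n, 0.2, 0.05), rnorm(n, 0.8, 0.05))
  pmin(pmax(v, 0), 1)
}

# synthetic stiffness matrix with one cluster sharing the global mixture
# and the others drawn from single components; returns the planted driver
make_driver_fixture <- function(sizes = c(20, 20, 20), seed = 1L) {
  set.seed(seed)
  n <- sum(sizes)
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- rmixture(n * (n - 1) / 2)
  assignment <- rep(seq_along(sizes), sizes)
  idx <- split(seq_len(n), assignment)
  fill_block <- function(M, ii, vals) {
    blk <- M[ii, ii]; blk[upper.tri(blk)] <- vals
    M[ii, ii] <- blk; M
  }
  np <- function(ii) length(ii) * (length(ii) - 1) / 2
  M <- fill_block(M, idx[[1]], rmixture(np(idx[[1]])))          # global-like
  M <- fill_block(M, idx[[2]], pmin(pmax(rnorm(np(idx[[2]]), 0.2, 0.05), 0), 1))
  M <- fill_block(M, idx[[3]], pmin(pmax(rnorm(np(idx[[3]]), 0.8, 0.05), 0), 1))
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 0
  dimnames(M) <- list(sprintf("n%03d", 1:n), sprintf("n%03d", 1:n))
  K <- springgeo:::new_stiffness_matrix(M, kernel_dim = NA_integer_,
                                        K_rescaled = M)
  list(K = K, assignment = assignment, driver = "1")
}
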