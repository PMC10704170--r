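# Radial-coordinate clustering and spectral baseline --------------------------

#' Radial coordinates of a hyperbolic embedding
#'
#' Poincare-ball norms \code{||x_i||}, all in [0, 1).  In hyperbolic network
#' models the radial coordinate encodes node popularity (expected degree
#' decays with radius).
#'
#' @param emb An \code{embedding} with \code{model$name == "hyperbolic"}.
#' @return Named numeric vector.
#' @export
radial_coordinates <- function(emb) {
  stopifnot(inherits(emb, "embedding"))
  if (emb$model$name != "hyperbolic") {
    stop("radial coordinates are defined for hyperbolic embeddings only")
  }
  r <- sqrt(rowSums(emb$coordinates^2))
  names(r) <- rownames(emb$coordinates)
  r
}

# k-means++ initialization followed by Lloyd iterations, best of `restarts`
# starts by total within-cluster sum of squares; X is an n x d matrix.
kmeanspp <- function(X, k, restarts = 25L, max_iter = 300L) {
  n <- nrow(X)
  best <- NULL
  for (s in seq_len(restarts)) {
    centers <- matrix(0, k, ncol(X))
    centers[1L, ] <- X[sample.int(n, 1L), ]
    d2 <- rowSums(sweep(X, 2, centers[1L, ])^2)
    if (k > 1) for (c in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[c, ] <- X[sample.int(n, 1L, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[c, ])^2))
    }
    assign <- integer(n)
    for (it in seq_len(max_iter)) {
      D2 <- outer(rowSums(X^2), rowSums(centers^2), `+`) -
        2 * tcrossprod(X, centers)
      new_assign <- max.col(-D2, ties.method = "first")
      for (c in which(tabulate(new_assign, k) == 0L)) {
        # re-seed an empty cluster at the point farthest from its center
        far <- which.max(D2[cbind(seq_len(n), new_assign)])
        new_assign[far] <- c
      }
      if (identical(new_assign, assign)) break
      assign <- new_assign
      for (c in seq_len(k)) {
        centers[c, ] <- colMeans(X[assign == c, , drop = FALSE])
      }
    }
    wss <- sum((X - centers[assign, , drop = FALSE])^2)
    if (is.null(best) || wss < best$wss - 1e-12) {
      best <- list(assign = assign, centers = centers, wss = wss)
    }
  }
  ctr <- colMeans(X)
  totss <- sum(sweep(X, 2, ctr)^2)
  best$bss <- totss - best$wss
  best$totss <- totss
  best
}

new_radial_clustering <- function(k, assignment, centroids, wss, bss,
                                  runs = 1L, wss_distribution = wss,
                                  bss_distribution = bss) {
  structure(list(k = as.integer(k), assignment = assignment,
                 centroids = centroids, wss = wss, bss = bss,
                 runs = as.integer(runs),
                 wss_distribution = wss_distribution,
                 bss_distribution = bss_distribution),
            class = "radial_clustering")
}

#' @export
print.radial_clustering <- function(x, ...) {
  cat(sprintf("radial_clustering: k = %d, wss = %.6g, bss = %.6g, runs = %d\n",
              x$k, x$wss, x$bss, x$runs))
  invisible(x)
}

# exact 1-D k-means by dynamic programming over contiguous partitions of the
# sorted values (optimal 1-D clusters are always contiguous); returns the
# layer-wise optimal WSS for every k' <= k, enabling a single-pass elbow scan
kmeans_dp_1d <- function(x, k) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  CS <- c(0, cumsum(xs)); CS2 <- c(0, cumsum(xs^2))
  seg_cost <- function(i, j) {  # vectorized over i
    s <- CS[j + 1L] - CS[i]
    s2 <- CS2[j + 1L] - CS2[i]
    pmax(s2 - s^2 / (j - i + 1), 0)
  }
  dp <- seg_cost(1L, seq_len(n))  # layer 1: dp[j] = cost(1..j)
  back <- matrix(1L, k, n)
  wss_by_k <- numeric(k)
  wss_by_k[1L] <- dp[n]
  if (k > 1) for (kk in 2:k) {
    new_dp <- rep(Inf, n)
    for (j in kk:n) {
      i <- kk:j
      cand <- dp[i - 1L] + seg_cost(i, j)
      b <- which.min(cand)
      new_dp[j] <- cand[b]
      back[kk, j] <- i[b]
    }
    dp <- new_dp
    wss_by_k[kk] <- dp[n]
  }
  bounds <- integer(k + 1L); bounds[k + 1L] <- n
  if (k > 1) for (kk in k:2) bounds[kk] <- back[kk, bounds[kk + 1L]] - 1L
  assign_sorted <- rep(seq_len(k), diff(bounds))
  assignment <- integer(n)
  assignment[ord] <- assign_sorted
  centroids <- vapply(seq_len(k), function(c) mean(xs[assign_sorted == c]), 0)
  list(assignment = assignment, centroids = centroids, wss = wss_by_k[k],
       wss_by_k = wss_by_k)
}

#' k-means on 1-D radial coordinates (exact)
#'
#' In one dimension the k-means optimum is attained on a contiguous
#' partition of the sorted values, so it is computed exactly by dynamic
#' programming rather than by stochastic Lloyd iterations (which remain in
#' use for the multi-dimensional spectral space).  Cluster labels are
#' numbered by increasing centroid.
#'
#' @param values Numeric vector (e.g. radial coordinates).
#' @param k Number of clusters.
#' @param restarts,seed Accepted for interface compatibility with the
#'   stochastic multi-dimensional solver; the exact 1-D solution does not
#'   depend on them.
#' @return A \code{radial_clustering}.
#' @export
kmeans_radial <- function(values, k, restarts = 25L, seed = 1L) {
  stopifnot(k >= 1, length(values) >= k)
  if (length(unique(values)) < k) {
    stop("k exceeds the number of distinct values")
  }
  fit <- kmeans_dp_1d(values, k)
  tot <- sum((values - mean(values))^2)
  new_radial_clustering(k, fit$assignment, fit$centroids,
                        fit$wss, tot - fit$wss)
}

#' Elbow method for the number of 1-D clusters
#'
#' Fits k-means for k = 1..k_max, records WSS(k), and returns the k whose
#' point (k, WSS(k)) is farthest (perpendicular distance) from the chord
#' joining (1, WSS(1)) and (k_max, WSS(k_max)).
#'
#' @param values Numeric vector.
#' @param k_max Largest k scanned (default 25).
#' @param restarts,seed Accepted for interface compatibility; the exact 1-D
#'   WSS curve does not depend on them.
#' @return Integer elbow k, with attribute \code{wss} (the WSS curve).
#' @export
elbow_k <- function(values, k_max = 25L, restarts = 10L, seed = 1L) {
  stopifnot(k_max >= 2, length(values) > k_max)
  if (length(unique(values)) == 1L) {
    warning("constant values: elbow undefined, returning 1")
    return(structure(1L, wss = rep(0, k_max)))
  }
  kmax_eff <- min(k_max, length(unique(values)))
  wss <- rep(NA_real_, k_max)
  wss[seq_len(kmax_eff)] <-
    kmeans_dp_1d(values, kmax_eff)$wss_by_k  # one DP pass gives every k
  p1 <- c(1, wss[1L]); p2 <- c(kmax_eff, wss[kmax_eff])
  v <- p2 - p1
  ks <- seq_len(kmax_eff)
  dist <- abs(v[2L] * (ks - p1[1L]) - v[1L] * (wss[ks] - p1[2L])) /
    sqrt(sum(v^2))
  if (max(dist) <= 1e-9 * max(wss[1L], 1)) {
    # degenerate (collinear) curve: take the smallest k that already
    # explains essentially all variance, else the trivial k = 1
    zero <- which(wss[ks] <= 1e-12 * max(wss[1L], 1))
    return(structure(as.integer(if (length(zero)) zero[1L] else 1L),
                     wss = wss))
  }
  structure(as.integer(which.max(dist)), wss = wss)
}

#' Stability analysis of the radial k-means clustering
#'
#' Repeats the k-means fit \code{runs} times with independent seeds derived
#' from the master seed and records the per-run within/between sums of
#' squares; summary includes the median BSS/WSS ratio (the clustering is
#' conventionally called stable when it is large, e.g. two orders of
#' magnitude).  With the exact 1-D solver the per-run values are constant
#' by construction; the distributions are still emitted so the protocol
#' matches repeated-run stability checks of stochastic k-means.
#'
#' @param values Numeric vector.
#' @param k Number of clusters.
#' @param runs Number of repetitions (default 1000; tests use fewer).
#' @param seed Master seed.
#' @param restarts Restarts per run.
#' @return A \code{radial_clustering} for the best run with
#'   \code{wss_distribution}, \code{bss_distribution} and attribute
#'   \code{median_bss_wss}.
#' @export
stability_analysis <- function(values, k, runs = 1000L, seed = 1L,
                               restarts = 1L) {
  stopifnot(runs >= 2)
  wss <- numeric(runs); bss <- numeric(runs)
  best <- NULL
  for (r in seq_len(runs)) {
    fit <- kmeans_radial(values, k, restarts = restarts,
                         seed = derive_seed(seed, r))
    wss[r] <- fit$wss; bss[r] <- fit$bss
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  out <- new_radial_clustering(k, best$assignment, best$centroids,
                               best$wss, best$bss, runs = runs,
                               wss_distribution = wss,
                               bss_distribution = bss)
  attr(out, "median_bss_wss") <- stats::median(bss / pmax(wss, .Machine$double.eps))
  out
}

# deterministic per-stage/run seed fan-out from a master seed (stays < 2^31)
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + 104729 * as.numeric(offset)) %%
               2147483647)
}

#' Intra-cluster pair counts over all node pairs
#'
#' For each cluster with n_c nodes: \code{n_c (n_c - 1) / 2} intra pairs;
#' the fraction is over all \code{n (n - 1) / 2} node pairs of the dense
#' stiffness matrix (not only graph edges).
#'
#' @param assignment Vector of cluster labels.
#' @return Data frame (cluster, size, intra_pairs, fraction) with attribute
#'   \code{total_pairs}.
#' @export
intra_cluster_pairs <- function(assignment) {
  n <- length(assignment)
  total <- n * (n - 1) / 2
  sizes <- table(assignment)
  df <- data.frame(cluster = names(sizes),
                   size = as.integer(sizes),
                   intra_pairs = as.numeric(sizes) * (as.numeric(sizes) - 1) / 2)
  df$fraction <- if (total > 0) df$intra_pairs / total else 0
  attr(df, "total_pairs") <- total
  df
}

# two-sample Kolmogorov-Smirnov statistic (ties allowed)
ks_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  max(abs(Fx - Fy))
}

#' Driver-cluster identification from stiffness distributions
#'
#' For every cluster with at least \code{min_pairs} intra-cluster pairs,
#' computes the two-sample Kolmogorov-Smirnov statistic between the
#' cluster's intra-pair rescaled stiffness values and the global
#' off-diagonal distribution.  The driver cluster is the one whose internal
#' distribution best recapitulates the global one, i.e. the minimum KS.
#'
#' @param K A \code{stiffness_matrix} with \code{K_rescaled}.
#' @param assignment Cluster labels in node order of K.
#' @param min_pairs Minimum intra pairs for a valid KS (default 30).
#' @return Object of class \code{driver_report}: list with \code{table}
#'   (cluster, size, intra_pairs, fraction, ks), \code{driver_cluster_id}
#'   (NA when no cluster qualifies), \code{global_values} and
#'   \code{intra_values} (named list) for density plotting.
#' @export
driver_cluster <- function(K, assignment, min_pairs = 30L) {
  stopifnot(inherits(K, "stiffness_matrix"))
  if (is.null(K$K_rescaled)) K <- rescale_stiffness(K)
  M <- K$K_rescaled
  stopifnot(length(assignment) == nrow(M))
  global <- M[upper.tri(M)]
  tab <- intra_cluster_pairs(assignment)
  tab$ks <- NA_real_
  intra_values <- list()
  for (r in seq_len(nrow(tab))) {
    idx <- which(assignment == tab$cluster[r])
    if (length(idx) < 2) next
    sub <- M[idx, idx]
    vals <- sub[upper.tri(sub)]
    intra_values[[as.character(tab$cluster[r])]] <- vals
    if (length(vals) >= min_pairs) tab$ks[r] <- ks_statistic(vals, global)
  }
  eligible <- which(!is.na(tab$ks))
  driver <- if (length(eligible) == 0L) {
    warning("no cluster reaches min_pairs = ", min_pairs,
            " intra pairs; no driver cluster identified")
    NA_character_
  } else {
    as.character(tab$cluster[eligible[which.min(tab$ks[eligible])]])
  }
  structure(list(table = tab, driver_cluster_id = driver,
                 global_values = global, intra_values = intra_values,
                 min_pairs = as.integer(min_pairs)),
            class = "driver_report")
}

#' @export
print.driver_report <- function(x, ...) {
  print(x$table)
  cat("driver cluster:", x$driver_cluster_id, "\n")
  invisible(x)
}

# symmetric normalized Laplacian; isolated (zero-degree) nodes removed
normalized_laplacian <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-8) stop("affinity matrix must be symmetric")
  if (any(W < 0)) stop("affinity matrix must be non-negative")
  deg <- rowSums(W)
  keep <- which(deg > 0)
  if (length(keep) < length(deg)) {
    warning(length(deg) - length(keep),
            " zero-degree node(s) removed before the Laplacian")
  }
  W <- W[keep, keep, drop = FALSE]
  dis <- 1 / sqrt(rowSums(W))
  L <- diag(length(keep)) - (dis * W) * rep(dis, each = length(keep))
  list(L = (L + t(L)) / 2, keep = keep)
}

#' Eigengap heuristic for the number of spectral clusters
#'
#' Eigenvalues of the symmetric normalized Laplacian sorted ascending;
#' returns the k <= k_max maximizing \code{lambda[k+1] - lambda[k]}.
#'
#' @param W Symmetric non-negative affinity matrix.
#' @param k_max Largest k considered (default 10).
#' @return Integer k with attribute \code{eigenvalues}.
#' @export
eigengap_k <- function(W, k_max = 10L) {
  nl <- normalized_laplacian(W)
  lam <- sort(eigen(nl$L, symmetric = TRUE, only.values = TRUE)$values)
  kk <- seq_len(min(k_max, length(lam) - 1L))
  gaps <- lam[kk + 1L] - lam[kk]
  structure(as.integer(which.max(gaps)), eigenvalues = lam)
}

#' Spectral clustering baseline
#'
#' Embeds the nodes with the first k eigenvectors (smallest eigenvalues) of
#' the symmetric normalized Laplacian, row-normalizes them to unit length,
#' and runs k-means++ in that spectral-coordinate space.  WSS/BSS are
#' measured in the same space.
#'
#' @param W Symmetric non-negative affinity matrix.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed.
#' @param restarts k-means restarts.
#' @return Object of class \code{spectral_baseline}: list with \code{k},
#'   \code{assignment} (NA for removed isolated nodes), \code{sizes},
#'   \code{wss}, \code{bss}, per-cluster \code{wss_by_cluster}.
#' @export
spectral_clustering <- function(W, k, seed = 1L, restarts = 25L) {
  n <- nrow(W)
  if (k < 2) stop("spectral baseline requires k >= 2")
  if (k > n) stop("k exceeds the number of nodes")
  nl <- normalized_laplacian(W)
  es <- eigen(nl$L, symmetric = TRUE)
  ord <- order(es$values)
  U <- es$vectors[, ord[seq_len(k)], drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  U <- U / ifelse(nrm > 0, nrm, 1)
  set.seed(seed)
  fit <- kmeanspp(U, k, restarts = restarts)
  assignment <- rep(NA_integer_, n)
  assignment[nl$keep] <- fit$assign
  wss_by_cluster <- vapply(seq_len(k), function(c) {
    idx <- fit$assign == c
    sum(sweep(U[idx, , drop = FALSE], 2, fit$centers[c, ])^2)
  }, 0)
  structure(list(k = as.integer(k), assignment = assignment,
                 sizes = tabulate(fit$assign, k), wss = fit$wss,
                 bss = fit$bss, wss_by_cluster = wss_by_cluster,
                 spectral_coords = U),
            class = "spectral_baseline")
}

#' @export
print.spectral_baseline <- function(x, ...) {
  cat(sprintf("spectral_baseline: k = %d, sizes = %s, wss = %.6g, bss = %.6g\n",
              x$k, paste(x$sizes, collapse = "/"), x$wss, x$bss))
  invisible(x)
}
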