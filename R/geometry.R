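# Metric models and embeddings ------------------------------------------------

#' Construct a metric model descriptor
#'
#' @param name One of "euclidean", "hyperbolic", "spherical".
#' @param curvature Curvature magnitude kappa for hyperbolic space (> 0;
#'   the Poincare ball model has constant curvature -kappa).
#' @param radius Sphere radius r for spherical geometry (> 0; curvature
#'   1 / r^2).
#' @return Object of class \code{metric_model}.
#' @export
metric_model <- function(name = c("euclidean", "hyperbolic", "spherical"),
                         curvature = 1, radius = 1) {
  name <- match.arg(name)
  stopifnot(curvature > 0, radius > 0)
  structure(list(name = name, curvature = curvature, radius = radius),
            class = "metric_model")
}

#' Geodesic distance between two points of a model space
#'
#' Euclidean: \code{||u - v||}.  Hyperbolic (Poincare ball, curvature
#' -kappa): \code{(1/sqrt(kappa)) * acosh(1 + 2||u-v||^2 /
#' ((1-||u||^2)(1-||v||^2)))}.  Spherical (radius r):
#' \code{r * acos(<u, v> / r^2)} with the cosine clamped to [-1, 1].
#'
#' @param u,v Coordinate vectors (ball coordinates for hyperbolic; points on
#'   the radius-r sphere for spherical).
#' @param model A \code{metric_model}.
#' @return Non-negative scalar distance.
#' @export
metric_distance <- function(u, v, model) {
  stopifnot(inherits(model, "metric_model"), length(u) == length(v))
  switch(model$name,
    euclidean = sqrt(sum((u - v)^2)),
    hyperbolic = {
      nu <- sum(u^2); nv <- sum(v^2)
      if (nu >= 1 || nv >= 1) stop("hyperbolic point outside the open unit ball")
      g <- 1 + 2 * sum((u - v)^2) / ((1 - nu) * (1 - nv))
      acosh(max(g, 1)) / sqrt(model$curvature)
    },
    spherical = {
      r <- model$radius
      if (abs(sqrt(sum(u^2)) - r) > 1e-6 * r ||
          abs(sqrt(sum(v^2)) - r) > 1e-6 * r) {
        stop("spherical point is not on the radius-", r, " sphere")
      }
      r * acos(min(max(sum(u * v) / r^2, -1), 1))
    })
}

#' Poincare disk distance in complex form
#'
#' The 2-D closed form \code{log((|1 - conj(a) b| + |b - a|) /
#' (|1 - conj(a) b| - |b - a|))}; for \code{a = 0} this reduces to
#' \code{log((1 + |b|) / (1 - |b|))}.  Used as an independent cross-check
#' of the n-dimensional acosh form.
#'
#' @param a,b Complex numbers with modulus < 1.
#' @return Hyperbolic distance (curvature -1).
#' @export
poincare_distance_complex <- function(a, b) {
  if (Mod(a) >= 1 || Mod(b) >= 1) stop("points must lie in the open unit disk")
  num <- Mod(1 - Conj(a) * b) + Mod(b - a)
  den <- Mod(1 - Conj(a) * b) - Mod(b - a)
  log(num / den)
}

# all-pairs distance matrix under a metric model; X is n x p coordinates
pairwise_model_distances <- function(X, model) {
  n <- nrow(X)
  switch(model$name,
    euclidean = as.matrix(stats::dist(X)),
    hyperbolic = {
      sq <- rowSums(X^2)
      if (any(sq >= 1)) stop("hyperbolic coordinates outside the open unit ball")
      E2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
      E2[E2 < 0] <- 0
      G <- 1 + 2 * E2 / outer(1 - sq, 1 - sq)
      D <- acosh(pmax(G, 1)) / sqrt(model$curvature)
      diag(D) <- 0
      D
    },
    spherical = {
      r <- model$radius
      Cc <- tcrossprod(X) / r^2
      Cc <- pmin(pmax(Cc, -1), 1)
      D <- r * acos(Cc)
      diag(D) <- 0
      D
    })
}

new_embedding <- function(coordinates, model, dimension, stress,
                          radial = NULL, details = list()) {
  structure(list(coordinates = coordinates, model = model,
                 dimension = as.integer(dimension), stress = stress,
                 radial = radial, details = details),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %s, p = %d, n = %d, stress = %.6g\n",
              x$model$name, x$dimension, nrow(x$coordinates), x$stress))
  invisible(x)
}

check_dissimilarity <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stop("dissimilarity matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("dissimilarity diagonal must be zero")
  if (any(D < 0)) stop("dissimilarities must be non-negative")
  (D + t(D)) / 2
}

#' Embedding stress (residual sum of squares)
#'
#' \code{sum over unordered pairs of (d_input - d_embedding)^2}, with the
#' embedded distances computed under the embedding's metric model.  A
#' normalized diagnostic \code{stress / sum(d_input^2)} is attached as an
#' attribute but never used for model selection.
#'
#' @param D Input dissimilarity matrix.
#' @param emb An \code{embedding}.
#' @return Non-negative scalar with attribute \code{normalized}.
#' @export
embedding_stress <- function(D, emb) {
  D <- check_dissimilarity(D)
  if (nrow(D) != nrow(emb$coordinates)) stop("dimension mismatch: D vs coordinates")
  Demb <- pairwise_model_distances(emb$coordinates, emb$model)
  ut <- upper.tri(D)
  s <- sum((D[ut] - Demb[ut])^2)
  attr(s, "normalized") <- s / sum(D[ut]^2)
  s
}

#' Classical MDS embedding into Euclidean space
#'
#' Torgerson scaling: double-center \code{-D^2 / 2}, eigendecompose, take
#' the top \code{p} non-negative eigenvalues (negative ones are clamped to
#' zero and counted).
#'
#' @param D Dissimilarity matrix (symmetric, zero diagonal).
#' @param p Embedding dimension, \code{2 <= p < n}.
#' @return An \code{embedding}; \code{details$negative_eigenvalues} counts
#'   clamped directions, radial coordinates are norms from the centroid.
#' @export
embed_euclidean <- function(D, p) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  if (p >= n) stop("embedding dimension p must be < number of points")
  if (p < 2) stop("embedding dimension p must be >= 2")
  B <- -0.5 * D^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))  # after row-centering this completes -J D^2 J / 2
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  lam <- es$values[seq_len(p)]
  n_neg <- sum(lam < 0)
  lam <- pmax(lam, 0)
  X <- es$vectors[, seq_len(p), drop = FALSE] %*% diag(sqrt(lam), p)
  rownames(X) <- rownames(D)
  model <- metric_model("euclidean")
  emb <- new_embedding(X, model, p, stress = NA_real_,
                       details = list(negative_eigenvalues = n_neg,
                                      eigenvalues = es$values))
  emb$stress <- as.numeric(embedding_stress(D, emb))
  ctr <- colMeans(X)
  emb$radial <- sqrt(rowSums(sweep(X, 2, ctr)^2))
  emb
}

# strain-minimizing initialization on the hyperboloid ("hydra"):
# Y = cosh(sqrt(kappa) D); leading eigenpair -> time-like component,
# most-negative eigenpairs -> spatial directions.
hydra_init <- function(D, p, kappa) {
  n <- nrow(D)
  Y <- cosh(sqrt(kappa) * D)
  es <- eigen(Y, symmetric = TRUE)
  lam <- es$values
  x0 <- pmax(sqrt(max(lam[1], 0)) * abs(es$vectors[, 1]), 1)
  neg <- which(lam < 0)
  neg <- neg[order(lam[neg])]           # most negative first
  take <- utils::head(neg, p)
  Xs <- matrix(0, n, p)
  if (length(take) > 0) {
    Xs[, seq_along(take)] <-
      es$vectors[, take, drop = FALSE] %*%
      diag(sqrt(-lam[take]), length(take))
  }
  if (length(take) < p) {
    warning("only ", length(take), " negative eigenvalues for ", p,
            " spatial directions; padding with zeros")
  }
  nrm <- sqrt(rowSums(Xs^2))
  dir <- Xs / ifelse(nrm > 0, nrm, 1)
  dir[nrm == 0, 1] <- 1
  r <- sqrt((x0 - 1) / (x0 + 1))
  r * dir
}

# stress and gradient over ball coordinates, with the unconstrained
# parametrization x = tanh(|y|) y / |y| keeping every point inside the ball
hyp_stress_objective <- function(D, n, p, kappa) {
  s <- 1 / sqrt(kappa)
  ut <- upper.tri(D)
  ball <- function(y) {
    Y <- matrix(y, n, p)
    r <- sqrt(rowSums(Y^2))
    f <- ifelse(r > 1e-8, tanh(r) / r, 1 - r^2 / 3)
    list(Y = Y, r = r, f = f, X = Y * f)
  }
  fn <- function(y) {
    X <- ball(y)$X
    sq <- rowSums(X^2)
    E2 <- pmax(outer(sq, sq, `+`) - 2 * tcrossprod(X), 0)
    G <- 1 + 2 * E2 / outer(1 - sq, 1 - sq)
    Dd <- s * acosh(pmax(G, 1))
    sum((D[ut] - Dd[ut])^2)
  }
  gr <- function(y) {
    b <- ball(y)
    X <- b$X
    sq <- rowSums(X^2)
    B <- 1 - sq
    E2 <- pmax(outer(sq, sq, `+`) - 2 * tcrossprod(X), 0)
    BB <- outer(B, B)
    G <- 1 + 2 * E2 / BB
    Dd <- s * acosh(pmax(G, 1))
    W <- 2 * (Dd - D) * s / sqrt(pmax(G^2 - 1, 1e-18))
    diag(W) <- 0
    M <- 4 * W / BB
    gX <- (rowSums(M)) * X - M %*% X +
      X * (4 / B^2) * as.vector((W * E2) %*% (1 / B))
    # chain rule through x = f(r) y / r
    r <- b$r; f <- b$f
    fp <- 1 - tanh(r)^2
    dot <- rowSums(gX * b$Y)
    safe_r2 <- pmax(r^2, 1e-16)
    gY <- f * gX + ((fp - f) * dot / safe_r2) * b$Y
    gY[r <= 1e-8, ] <- gX[r <= 1e-8, , drop = FALSE]
    as.vector(gY)
  }
  list(fn = fn, gr = gr)
}

#' Hyperbolic embedding into the Poincare ball
#'
#' Strain-minimizing eigendecomposition initialization followed (by
#' default) by quasi-Newton minimization of the raw stress over ball
#' coordinates, using a smooth unconstrained parametrization that keeps all
#' points strictly inside the unit ball.
#'
#' @param D Dissimilarity matrix.
#' @param p Ball dimension (>= 2).
#' @param kappa Curvature magnitude (> 0), default 1.
#' @param refine Run the stress-minimizing refinement (default TRUE).
#' @param maxit Maximum refinement iterations.
#' @return An \code{embedding} with radial coordinates \code{||x_i||}.
#' @export
embed_hyperbolic <- function(D, p, kappa = 1, refine = TRUE, maxit = 500L) {
  D <- check_dissimilarity(D)
  stopifnot(p >= 2, kappa > 0)
  n <- nrow(D)
  X <- hydra_init(D, p, kappa)
  rmax <- 1 - 1e-6
  nrm <- sqrt(rowSums(X^2))
  shrink <- ifelse(nrm > rmax, rmax / nrm, 1)
  X <- X * shrink
  model <- metric_model("hyperbolic", curvature = kappa)
  iters <- 0L
  if (refine && n > 1) {
    obj <- hyp_stress_objective(D, n, p, kappa)
    nrm <- pmin(sqrt(rowSums(X^2)), rmax)
    y0 <- X * ifelse(nrm > 0, atanh(nrm) / pmax(nrm, 1e-300), 1)
    opt <- stats::optim(as.vector(y0), obj$fn, obj$gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 10, pgtol = 0))
    Y <- matrix(opt$par, n, p)
    r <- sqrt(rowSums(Y^2))
    f <- ifelse(r > 1e-8, tanh(r) / r, 1 - r^2 / 3)
    X <- Y * f
    iters <- opt$counts[[1L]]
  }
  rownames(X) <- rownames(D)
  emb <- new_embedding(X, model, p, stress = NA_real_,
                       radial = sqrt(rowSums(X^2)),
                       details = list(refined = refine, iterations = iters))
  emb$stress <- as.numeric(embedding_stress(D, emb))
  emb
}

#' Spherical embedding with curvature-radius optimization
#'
#' Searches the sphere radius r over \code{[max(D)/pi (1 + eps),
#' 10 max(D)]} minimizing \code{|lambda_min(Z(r))|} with
#' \code{Z(r) = r^2 cos(D / r)} (log-spaced grid plus local refinement);
#' at the optimum, eigendecomposes Z, takes the top-p non-negative
#' eigenpairs and projects every point onto the radius-r sphere.
#'
#' @param D Dissimilarity matrix.
#' @param p Ambient embedding dimension (points on the sphere S^(p-1)).
#' @param n_grid Number of log-spaced radii scanned before refinement.
#' @return An \code{embedding}; \code{details$r_star} holds the optimal
#'   radius.
#' @export
embed_spherical <- function(D, p, n_grid = 120L) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  if (p >= n) stop("embedding dimension p must be < number of points")
  dmax <- max(D)
  if (dmax <= 0) stop("degenerate dissimilarity matrix (all zeros)")
  lo <- dmax / pi * (1 + 1e-6)
  hi <- 10 * dmax
  obj <- function(r) {
    Z <- r^2 * cos(D / r)
    if (any(!is.finite(Z))) stop("non-finite entries in Z(r)")
    abs(min(eigen(Z, symmetric = TRUE, only.values = TRUE)$values))
  }
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  vals <- vapply(grid, obj, 0)
  i <- which.min(vals)
  if (i == 1L || i == n_grid) {
    warning("radius search hit the bracket boundary; ",
            "dissimilarities may not fit any sphere in range")
  }
  bl <- grid[max(i - 1L, 1L)]; bu <- grid[min(i + 1L, n_grid)]
  r_star <- if (bl < bu) {
    stats::optimize(function(t) obj(exp(t)), c(log(bl), log(bu)),
                    tol = 1e-10)$minimum
  } else log(grid[i])
  r_star <- exp(r_star)
  if (obj(grid[i]) < obj(r_star)) r_star <- grid[i]
  Z <- r_star^2 * cos(D / r_star)
  es <- eigen(Z, symmetric = TRUE)
  lam <- pmax(es$values[seq_len(p)], 0)
  X <- es$vectors[, seq_len(p), drop = FALSE] %*% diag(sqrt(lam), p)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  if (any(zero)) X[zero, 1] <- 1
  nrm[zero] <- 1
  X <- X * (r_star / nrm)
  rownames(X) <- rownames(D)
  model <- metric_model("spherical", radius = r_star)
  emb <- new_embedding(X, model, p, stress = NA_real_,
                       details = list(r_star = r_star,
                                      lambda_min = min(es$values)))
  emb$stress <- as.numeric(embedding_stress(D, emb))
  emb
}

#' Embed in all candidate geometries and select the minimum-stress one
#'
#' Runs every (model, dimension) combination, tabulates the raw stress, and
#' flags the minimum.  An embedding failure is recorded as a missing row
#' with a warning; the sweep never aborts.
#'
#' @param D Dissimilarity matrix.
#' @param dims Integer vector of dimensions (default 3:10).
#' @param models Character vector of model names to try.
#' @param kappa Hyperbolic curvature magnitude.
#' @param refine Refine the hyperbolic embedding.
#' @return Object of class \code{stress_table}: data frame of (model,
#'   dimension, stress) with attributes \code{best_model},
#'   \code{best_dimension} and \code{embeddings} (named list).
#' @export
select_geometry <- function(D, dims = 3:10,
                            models = c("euclidean", "hyperbolic", "spherical"),
                            kappa = 1, refine = TRUE) {
  D <- check_dissimilarity(D)
  stopifnot(length(dims) > 0)
  rows <- list(); embs <- list()
  for (model in models) {
    for (p in dims) {
      key <- paste0(model, "_", p)
      emb <- tryCatch(
        switch(model,
               euclidean = embed_euclidean(D, p),
               hyperbolic = embed_hyperbolic(D, p, kappa = kappa, refine = refine),
               spherical = embed_spherical(D, p)),
        error = function(e) {
          warning("embedding failed for ", key, ": ", conditionMessage(e))
          NULL
        })
      if (is.null(emb)) next
      rows[[key]] <- data.frame(model = model, dimension = p,
                                stress = emb$stress)
      embs[[key]] <- emb
    }
  }
  if (length(rows) == 0L) stop("every embedding in the sweep failed")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- which.min(tab$stress)
  attr(tab, "best_model") <- tab$model[best]
  attr(tab, "best_dimension") <- tab$dimension[best]
  attr(tab, "embeddings") <- embs
  class(tab) <- c("stress_table", "data.frame")
  tab
}

#' @export
print.stress_table <- function(x, ...) {
  print.data.frame(x, ...)
  cat(sprintf("best: %s (p = %d)\n",
              attr(x, "best_model"), attr(x, "best_dimension")))
  invisible(x)
}
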