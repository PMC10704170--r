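# Planted-geometry generators and hand-checkable fixtures ---------------------

#' Sample points from a model space
#'
#' Euclidean: uniform in the box \code{[0, box]^dim}.  Spherical: uniform
#' on the radius-r sphere S^dim in R^(dim+1) (normalized Gaussian draws).
#' Hyperbolic (dim = 2 only): angle uniform, native radius with density
#' proportional to sinh(r) on [0, R] (quasi-uniform in hyperbolic area),
#' returned in Poincare-ball coordinates.
#'
#' @param model Model name or \code{metric_model}.
#' @param n Number of points (>= 3).
#' @param dim Intrinsic dimension (>= 2; hyperbolic supports 2 only).
#' @param params List of model parameters: \code{box} (euclidean, default
#'   1), \code{radius} (spherical, default 1), \code{R} (hyperbolic native
#'   disk radius, default 3).
#' @param seed Integer seed.
#' @return Object of class \code{planted_configuration}: list with
#'   \code{model} (a \code{metric_model}), \code{coords},
#'   \code{true_distances}, \code{seed}, \code{params}.
#' @export
sample_points <- function(model, n, dim = 2L, params = list(), seed = 1L) {
  stopifnot(n >= 3, dim >= 2)
  name <- if (inherits(model, "metric_model")) model$name else model
  set.seed(seed)
  if (name == "euclidean") {
    box <- params$box %||% 1
    X <- matrix(stats::runif(n * dim, 0, box), n, dim)
    mm <- metric_model("euclidean")
  } else if (name == "spherical") {
    r <- params$radius %||% 1
    X <- matrix(stats::rnorm(n * (dim + 1L)), n, dim + 1L)
    X <- X * (r / sqrt(rowSums(X^2)))
    mm <- metric_model("spherical", radius = r)
  } else if (name == "hyperbolic") {
    if (dim != 2L) stop("hyperbolic sampling is implemented for dim = 2 only")
    R <- params$R %||% 3
    u <- stats::runif(n)
    rnat <- acosh(1 + u * (cosh(R) - 1))   # density ~ sinh(r) on [0, R]
    theta <- stats::runif(n, 0, 2 * pi)
    rho <- tanh(rnat / 2)                  # ball radius at curvature -1
    X <- cbind(rho * cos(theta), rho * sin(theta))
    mm <- metric_model("hyperbolic", curvature = 1)
  } else stop("unsupported model: ", name)
  rownames(X) <- sprintf("n%04d", seq_len(n))
  D <- pairwise_model_distances(X, mm)
  dimnames(D) <- list(rownames(X), rownames(X))
  structure(list(model = mm, coords = X, true_distances = D,
                 seed = as.integer(seed),
                 params = list(n = n, dim = dim, params = params)),
            class = "planted_configuration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dissimilarity matrix of a planted configuration
#'
#' Exact model-space pairwise distances, optionally perturbed by
#' multiplicative log-normal noise (preserves positivity and symmetry; the
#' diagonal stays zero).
#'
#' @param cfg A \code{planted_configuration}.
#' @param noise_sd Standard deviation of the log-normal factor (0 = exact).
#' @param seed Seed for the noise draws.
#' @return Symmetric zero-diagonal dissimilarity matrix.
#' @export
planted_dissimilarity <- function(cfg, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(cfg, "planted_configuration"))
  D <- cfg$true_distances
  if (noise_sd > 0) {
    set.seed(seed)
    n <- nrow(D)
    eps <- matrix(1, n, n)
    eps[upper.tri(eps)] <- stats::rlnorm(n * (n - 1) / 2, 0, noise_sd)
    eps[lower.tri(eps)] <- t(eps)[lower.tri(eps)]
    D <- D * eps
    diag(D) <- 0
  }
  D
}

#' Threshold graph of a planted configuration
#'
#' Connects every pair at true distance below \code{threshold}.  On a
#' hyperbolic disk this yields the heavy-tailed degree sequences typical of
#' hyperbolic random graphs.
#'
#' @param cfg A \code{planted_configuration}.
#' @param threshold Connection radius (> 0).
#' @return A \code{gene_network} with node ids "n0001", ...
#' @export
geometric_graph <- function(cfg, threshold) {
  stopifnot(inherits(cfg, "planted_configuration"), threshold > 0)
  D <- cfg$true_distances
  n <- nrow(D)
  pairs <- which(upper.tri(D) & D < threshold, arr.ind = TRUE)
  if (nrow(pairs) == 0L) stop("threshold graph is empty")
  edges <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  new_gene_network(rownames(D), edges)
}

#' Tiny hand-checkable fixture graphs
#'
#' Named set of small graphs with closed-form expected spring-model values
#' attached (attribute \code{expected}): single edge \code{p2}, triangle
#' \code{k3}, 3-leaf star \code{star3}, path \code{p5}, two 10-cliques
#' disjoint (\code{cliques10_disjoint}) and joined by one bridge edge
#' (\code{cliques10_bridged}).  For a connected graph the expected
#' stiffness is the closed form \code{k_ij = (1/(m_i m_j)) / sum(1/m^2)}.
#'
#' @return Named list of \code{gene_network} objects.
#' @export
fixture_graphs <- function() {
  mk <- function(ids, edges) new_gene_network(ids, as.matrix(edges))
  clique_edges <- function(idx) t(utils::combn(idx, 2))
  g <- list(
    p2 = mk(c("a", "b"), cbind(1L, 2L)),
    k3 = mk(c("a", "b", "c"), rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))),
    star3 = mk(c("hub", "l1", "l2", "l3"),
               rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L))),
    p5 = mk(paste0("v", 1:5), cbind(1:4, 2:5)),
    cliques10_disjoint = mk(sprintf("c%02d", 1:20),
                            rbind(clique_edges(1:10), clique_edges(11:20))),
    cliques10_bridged = mk(sprintf("c%02d", 1:20),
                           rbind(clique_edges(1:10), clique_edges(11:20),
                                 c(10L, 11L)))
  )
  for (nm in names(g)) {
    gg <- g[[nm]]
    m <- suppressWarnings(node_masses(gg))
    comp <- graph_components(gg)
    Kexp <- matrix(0, n_nodes(gg), n_nodes(gg),
                   dimnames = list(gg$node_ids, gg$node_ids))
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      v <- 1 / m[idx]
      Kexp[idx, idx] <- outer(v, v) / sum(v^2)
    }
    attr(g[[nm]], "expected") <- list(masses = m, stiffness = Kexp,
                                      kernel_dim = length(unique(comp)))
  }
  g
}
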