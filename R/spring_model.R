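# Spring-network stiffness ----------------------------------------------------
#
# The network is a system of masses (nodes, mass = total degree) and springs
# (edges).  At mechanical equilibrium the generalized Hooke law forces the
# stiffness operator into the nullspace of the transposed mass-weighted
# incidence matrix; an orthonormal basis N of that nullspace yields the
# all-pairs stiffness K = N %*% t(N).

#' Vibrational centrality
#'
#' Displacement amplitude of each node under a thermal bath of temperature
#' \code{T}: \code{sqrt((T / k0) * Lplus[i, i])} where \code{Lplus} is the
#' Moore-Penrose pseudoinverse of the unweighted graph Laplacian and
#' \code{k0} the common spring stiffness.
#'
#' @param g A \code{gene_network}.
#' @param temperature Bath temperature (> 0).
#' @param k0 Common spring stiffness (> 0).
#' @return Named numeric vector of displacements.
#' @export
vibrational_centrality <- function(g, temperature = 1, k0 = 1) {
  stopifnot(temperature > 0, k0 > 0)
  n <- n_nodes(g)
  if (n == 0L) stop("empty graph")
  L <- laplacian_matrix(g)
  Ld <- pinv_diag(L)
  out <- sqrt((temperature / k0) * pmax(Ld, 0))
  names(out) <- g$node_ids
  out
}

laplacian_matrix <- function(g) {
  n <- n_nodes(g)
  L <- matrix(0, n, n, dimnames = list(g$node_ids, g$node_ids))
  for (e in seq_len(n_edges(g))) {
    i <- g$edges[e, 1L]; j <- g$edges[e, 2L]
    L[i, j] <- L[i, j] - 1; L[j, i] <- L[j, i] - 1
    L[i, i] <- L[i, i] + 1; L[j, j] <- L[j, j] + 1
  }
  L
}

# diagonal of the Moore-Penrose pseudoinverse of a symmetric PSD matrix
pinv_diag <- function(S, tol = 1e-10) {
  es <- eigen(S, symmetric = TRUE)
  lam <- es$values
  keep <- lam > tol * max(abs(lam), 1)
  V <- es$vectors[, keep, drop = FALSE]
  rowSums(sweep(V^2, 2, lam[keep], `/`))
}

#' Mass-weighted incidence matrix
#'
#' Row-scales the oriented incidence matrix by the node masses:
#' \code{C[i, e] = m_i * A[i, e]}.
#'
#' @param A Oriented incidence matrix (nodes x edges).
#' @param m Mass vector (length = nrow(A)).
#' @return Weighted incidence matrix with the same shape and dimnames.
#' @export
weighted_incidence <- function(A, m) {
  stopifnot(length(m) == nrow(A))
  incident <- rowSums(A != 0) > 0
  if (any(m[incident] <= 0)) {
    stop("node with zero/negative mass has incident edges")
  }
  A * m
}

new_stiffness_matrix <- function(K, kernel_dim, K_rescaled = NULL) {
  structure(list(K = K, K_rescaled = K_rescaled,
                 kernel_dim = as.integer(kernel_dim)),
            class = "stiffness_matrix")
}

#' @export
print.stiffness_matrix <- function(x, ...) {
  cat("stiffness_matrix:", nrow(x$K), "nodes, kernel_dim =", x$kernel_dim,
      if (is.null(x$K_rescaled)) "(raw)\n" else "(rescaled available)\n")
  invisible(x)
}

#' Equilibrium stiffness matrix from the nullspace of C-transpose
#'
#' Computes an orthonormal basis N of the node-space nullspace of
#' \code{t(C)} (vectors v with \code{m_i v_i = m_j v_j} on every edge) by
#' singular-value decomposition, and returns the projector
#' \code{K = N %*% t(N)} as the all-pairs stiffness.  For a connected graph
#' the kernel is spanned by \code{v_i = 1 / m_i}, giving
#' \code{k_ij = (1 / (m_i m_j)) / sum(1 / m^2)}.
#'
#' @param C Weighted incidence matrix (nodes x edges).
#' @param tol Relative singular-value threshold for the numerical nullspace.
#' @return A \code{stiffness_matrix} with raw \code{K} and
#'   \code{kernel_dim}; row/col names taken from \code{C}.
#' @export
stiffness_equilibrium <- function(C, tol = 1e-10) {
  if (all(C == 0)) stop("weighted incidence is all zero")
  Ct <- t(C)
  sv <- svd(Ct, nu = 0, nv = ncol(Ct))
  smax <- max(sv$d)
  null_idx <- c(which(sv$d <= tol * smax),
                seq_len(ncol(Ct))[seq_len(ncol(Ct)) > length(sv$d)])
  if (length(null_idx) == 0L) {
    stop("empty nullspace of t(C): no equilibrium stiffness exists")
  }
  N <- sv$v[, null_idx, drop = FALSE]
  K <- N %*% t(N)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(C), rownames(C))
  out <- new_stiffness_matrix(K, kernel_dim = length(null_idx))
  out$kernel_basis <- N
  out
}

#' Non-equilibrium stiffness
#'
#' When the node forces do not balance, the equilibrium relation is replaced
#' by the least-squares solve \code{t(C) K = F_edge \%*\% diag(1/delta_x)},
#' where row e of \code{F_edge} restricts the node forces to the endpoints
#' of edge e.  \code{t(C)} has rank at most n - 1, so its Moore-Penrose
#' pseudoinverse is used (with a warning) and the result symmetrized.
#'
#' @param C Weighted incidence matrix (nodes x edges).
#' @param f_nodes Per-node force vector.
#' @param delta_x Per-node displacements (vibrational centralities); must be
#'   non-zero everywhere.
#' @return A \code{stiffness_matrix} (kernel_dim = NA: not nullspace based).
#' @export
stiffness_nonequilibrium <- function(C, f_nodes, delta_x) {
  n <- nrow(C); m <- ncol(C)
  stopifnot(length(f_nodes) == n, length(delta_x) == n)
  if (any(delta_x == 0)) {
    stop("delta_x must be non-zero on every node (diag(delta_x) invertible)")
  }
  warning("t(C) is singular (rank <= n - 1); using Moore-Penrose pseudoinverse")
  Fedge <- (t(C) != 0) * rep(f_nodes, each = m)
  rhs <- sweep(Fedge, 2, delta_x, `/`)
  K <- mp_pinv(t(C)) %*% rhs
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(C), rownames(C))
  new_stiffness_matrix(K, kernel_dim = NA_integer_)
}

mp_pinv <- function(X, tol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) return(t(X) * 0)
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Min-max rescale the off-diagonal stiffness values to [0, 1]
#'
#' @param K A \code{stiffness_matrix}.
#' @return The same object with \code{K_rescaled} filled.  If all
#'   off-diagonal values are equal, every rescaled value is set to 1 with a
#'   warning.
#' @export
rescale_stiffness <- function(K) {
  stopifnot(inherits(K, "stiffness_matrix"))
  M <- K$K
  off <- M[upper.tri(M)]
  lo <- min(off); hi <- max(off)
  R <- M
  if (hi - lo <= 1e-12 * max(abs(hi), abs(lo), 1)) {
    warning("degenerate rescale: all off-diagonal stiffness values equal; ",
            "setting all rescaled values to 1")
    R[] <- 1
  } else {
    R <- (M - lo) / (hi - lo)
  }
  diag(R) <- diag(M)  # diagonal never used downstream
  K$K_rescaled <- pmin(pmax(R, 0), 1)
  K
}

#' Stiffness-derived dissimilarity matrix
#'
#' \code{d_ij = 1 / (1 + k_ij)} on the rescaled stiffness, so stiff (highly
#' interacting) pairs are close.  Off-diagonal values lie in [0.5, 1]; the
#' diagonal is forced to 0.
#'
#' @param K A \code{stiffness_matrix} with \code{K_rescaled} available (it
#'   is computed on the fly otherwise).
#' @return Symmetric zero-diagonal dissimilarity matrix.
#' @export
stiffness_to_dissimilarity <- function(K) {
  stopifnot(inherits(K, "stiffness_matrix"))
  if (is.null(K$K_rescaled)) K <- rescale_stiffness(K)
  D <- 1 / (1 + K$K_rescaled)
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Write / read a square symmetric matrix as CSV with node-id header
#'
#' @param M Square matrix with dimnames.
#' @param path CSV path.
#' @export
write_matrix_csv <- function(M, path) {
  df <- as.data.frame(M)
  utils::write.csv(cbind(node_id = rownames(M), df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1L]]
  M <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(M) <- list(ids, ids)
  M
}
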