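# SIF parsing and graph construction -----------------------------------------

#' Pathway Commons interaction types
#'
#' The eleven binary interaction types emitted by Pathway Commons SIF exports
#' that are retained when building a gene network.
#'
#' @return Character vector of length 11.
#' @export
pc_interaction_types <- function() {
  c("interacts-with", "in-complex-with", "catalysis-precedes",
    "controls-state-change-of", "controls-transport-of",
    "controls-transport-of-chemical", "controls-expression-of",
    "controls-phosphorylation-of", "controls-production-of",
    "chemical-affects", "consumption-controlled-by")
}

#' Parse a SIF interaction table
#'
#' Reads a Simple Interaction Format file: tab-separated lines of
#' \code{participantA <TAB> interaction-type <TAB> participantB}.  Extended
#' SIF columns beyond the third are ignored; blank lines are skipped.
#'
#' @param path Path to a SIF file.
#' @return An object of class \code{interaction_table}: a data frame with
#'   columns \code{participant_a}, \code{interaction_type},
#'   \code{participant_b} and attribute \code{source_path}.
#' @export
parse_sif <- function(path) {
  if (!file.exists(path)) stop("SIF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("empty SIF file: ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- keep[which(nf < 3L)[1L]]
    stop("malformed SIF line ", bad, ": fewer than 3 tab-separated fields")
  }
  a <- vapply(fields, `[[`, "", 1L)
  ty <- vapply(fields, `[[`, "", 2L)
  b <- vapply(fields, `[[`, "", 3L)
  if (any(!nzchar(a) | !nzchar(ty) | !nzchar(b))) {
    bad <- keep[which(!nzchar(a) | !nzchar(ty) | !nzchar(b))[1L]]
    stop("malformed SIF line ", bad, ": empty field")
  }
  tab <- data.frame(participant_a = a, interaction_type = ty,
                    participant_b = b, stringsAsFactors = FALSE)
  attr(tab, "source_path") <- path
  class(tab) <- c("interaction_table", "data.frame")
  tab
}

#' Build a simple undirected gene network from an interaction table
#'
#' Rows whose interaction type is not in \code{allowed_types} are dropped,
#' edges are made undirected, parallel edges are collapsed to one, and
#' self-loops are removed (and counted).  Node order is lexicographic so
#' downstream matrices are bit-reproducible.
#'
#' @param table An \code{interaction_table} (or any data frame with the same
#'   three columns).
#' @param allowed_types Character vector of interaction types to keep.
#' @return Object of class \code{gene_network}: list with \code{node_ids}
#'   (sorted), \code{edges} (m x 2 integer matrix, i < j, ordered),
#'   \code{multi_edge_count} (non-loop rows before collapsing) and
#'   \code{self_loop_count}.
#' @export
build_graph <- function(table, allowed_types = pc_interaction_types()) {
  stopifnot(length(allowed_types) > 0L)
  keep <- table$interaction_type %in% allowed_types
  a <- table$participant_a[keep]
  b <- table$participant_b[keep]
  loop <- a == b
  self_loop_count <- sum(loop)
  a <- a[!loop]; b <- b[!loop]
  if (length(a) == 0L) stop("no edges survive the interaction-type filter")
  node_ids <- sort(unique(c(a, b)), method = "radix")
  ia <- match(a, node_ids); ib <- match(b, node_ids)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  multi_edge_count <- length(lo)
  key <- (lo - 1) * length(node_ids) + hi
  dup <- duplicated(key)
  edges <- cbind(lo[!dup], hi[!dup])
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  new_gene_network(node_ids, edges, multi_edge_count, self_loop_count)
}

new_gene_network <- function(node_ids, edges, multi_edge_count = nrow(edges),
                             self_loop_count = 0L) {
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("i", "j")
  structure(list(node_ids = node_ids, edges = edges,
                 multi_edge_count = as.integer(multi_edge_count),
                 self_loop_count = as.integer(self_loop_count)),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$node_ids), "nodes,", nrow(x$edges), "edges",
      sprintf("(from %d parallel edges, %d self-loops dropped)\n",
              x$multi_edge_count, x$self_loop_count))
  invisible(x)
}

n_nodes <- function(g) length(g$node_ids)
n_edges <- function(g) nrow(g$edges)

#' Node masses (total degree)
#'
#' In the spring model each node carries a mass equal to its total degree in
#' the simplified graph, encoding the node's inertia to propagation of
#' elastic force.
#'
#' @param g A \code{gene_network}.
#' @return Named numeric vector of degrees.  Isolated nodes get mass 0 with
#'   a warning; they must be excluded before the spring model.
#' @export
node_masses <- function(g) {
  m <- numeric(n_nodes(g))
  for (col in 1:2) {
    t <- tabulate(g$edges[, col], nbins = n_nodes(g))
    m <- m + t
  }
  names(m) <- g$node_ids
  if (any(m == 0)) {
    warning(sum(m == 0), " isolated node(s) with mass 0; ",
            "exclude before the spring model")
  }
  m
}

#' Oriented incidence matrix
#'
#' Node-by-edge matrix with +1 at the lexicographically lower endpoint
#' (tail) and -1 at the higher (head) of each edge.  The orientation is a
#' bookkeeping choice; the downstream stiffness is provably orientation
#' invariant.
#'
#' @param g A \code{gene_network}.
#' @return Dense numeric matrix, nodes x edges, with node ids as rownames.
#' @export
oriented_incidence <- function(g) {
  n <- n_nodes(g); m <- n_edges(g)
  A <- matrix(0, n, m, dimnames = list(g$node_ids, NULL))
  if (m > 0) {
    A[cbind(g$edges[, 1L], seq_len(m))] <- 1
    A[cbind(g$edges[, 2L], seq_len(m))] <- -1
  }
  A
}

#' Write a gene network to SIF
#'
#' @param g A \code{gene_network}.
#' @param path Output file path.
#' @param type Interaction type used for every edge.
#' @export
write_sif <- function(g, path, type = "interacts-with") {
  a <- g$node_ids[g$edges[, 1L]]
  b <- g$node_ids[g$edges[, 2L]]
  writeLines(paste(a, type, b, sep = "\t"), path)
  invisible(path)
}

#' Export the edge list and node table
#'
#' @param g A \code{gene_network}.
#' @param edge_path,node_path Output CSV paths (NULL to skip).
#' @return Invisibly, list with the two data frames.
#' @export
write_network_tables <- function(g, edge_path = NULL, node_path = NULL) {
  edges <- data.frame(node_a = g$node_ids[g$edges[, 1L]],
                      node_b = g$node_ids[g$edges[, 2L]])
  deg <- suppressWarnings(node_masses(g))
  nodes <- data.frame(node_id = g$node_ids, degree = as.integer(deg))
  if (!is.null(edge_path)) utils::write.csv(edges, edge_path, row.names = FALSE)
  if (!is.null(node_path)) utils::write.csv(nodes, node_path, row.names = FALSE)
  invisible(list(edges = edges, nodes = nodes))
}

# connected components by repeated BFS over the edge list
graph_components <- function(g) {
  n <- n_nodes(g)
  adj <- vector("list", n)
  for (e in seq_len(n_edges(g))) {
    i <- g$edges[e, 1L]; j <- g$edges[e, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}
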