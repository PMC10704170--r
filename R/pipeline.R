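# Configuration-driven pipeline and CLI ---------------------------------------

#' Build and validate a pipeline configuration
#'
#' All knobs of the full analysis in one validated object.  Exactly one
#' input among \code{sif}, \code{dissimilarity_csv}, \code{synthetic} must
#' be given.
#'
#' @param sif Path to a SIF interaction file.
#' @param dissimilarity_csv Path to a precomputed square dissimilarity CSV.
#' @param synthetic List for a planted run: \code{model}, \code{n},
#'   \code{dim}, \code{params}, \code{threshold} (build a threshold graph)
#'   or \code{threshold = NULL} (use exact distances directly).
#' @param allowed_types SIF interaction types to keep.
#' @param temperature,k0 Spring-model bath temperature and common stiffness.
#' @param tol Nullspace singular-value threshold.
#' @param dims Embedding dimension sweep.
#' @param kappa Hyperbolic curvature magnitude.
#' @param refine Refine the hyperbolic embedding.
#' @param models Geometries to sweep.
#' @param k_max Elbow search bound.
#' @param restarts k-means restarts.
#' @param stability_runs Repetitions of the stability analysis.
#' @param min_pairs Minimum intra-cluster pairs for the driver KS.
#' @param seed Master seed (fans out to per-stage seeds).
#' @param outdir Output directory.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sif = NULL, dissimilarity_csv = NULL,
                            synthetic = NULL,
                            allowed_types = pc_interaction_types(),
                            temperature = 1, k0 = 1, tol = 1e-10,
                            dims = 3:10, kappa = 1, refine = TRUE,
                            models = c("euclidean", "hyperbolic", "spherical"),
                            k_max = 25L, restarts = 25L,
                            stability_runs = 1000L, min_pairs = 30L,
                            seed = 1L, outdir = "springgeo_out") {
  inputs <- !vapply(list(sif, dissimilarity_csv, synthetic), is.null, NA)
  if (sum(inputs) != 1L) {
    stop("exactly one of sif, dissimilarity_csv, synthetic must be given")
  }
  if (!is.null(synthetic)) {
    known <- c("model", "n", "dim", "params", "threshold")
    bad <- setdiff(names(synthetic), known)
    if (length(bad)) stop("unknown synthetic keys: ", paste(bad, collapse = ", "))
  }
  stopifnot(temperature > 0, k0 > 0, tol > 0, length(dims) > 0,
            all(dims >= 2), kappa > 0, k_max >= 2, restarts >= 1,
            stability_runs >= 2, min_pairs >= 1)
  structure(list(sif = sif, dissimilarity_csv = dissimilarity_csv,
                 synthetic = synthetic, allowed_types = allowed_types,
                 temperature = temperature, k0 = k0, tol = tol,
                 dims = as.integer(dims), kappa = kappa, refine = refine,
                 models = models, k_max = as.integer(k_max),
                 restarts = as.integer(restarts),
                 stability_runs = as.integer(stability_runs),
                 min_pairs = as.integer(min_pairs),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Keys mirror the arguments of \code{\link{pipeline_config}}; unknown keys
#' are rejected.
#'
#' @param path JSON file path.
#' @param ... Overrides applied after reading.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  over <- list(...)
  raw[names(over)] <- over
  do.call(pipeline_config, raw)
}

#' Run the full latent-geometry pipeline
#'
#' Network construction (SIF, CSV or synthetic) -> spring-model stiffness
#' -> dissimilarity -> embedding sweep over all models and dimensions ->
#' minimum-stress geometry selection -> if the best geometry is hyperbolic:
#' radial clustering with elbow, stability, driver report, and the
#' spectral-clustering baseline.  All outputs are CSV/JSON files under
#' \code{config$outdir}; a manifest records the seed, a config hash, the
#' md5 of every output, and per-stage wall times.
#'
#' @param config A \code{pipeline_config}.
#' @return The manifest, invisibly (also written as manifest.json).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("springgeo")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed,
                   config = config[setdiff(names(config), "outdir")],
                   stages = list(), files = list())
  out <- function(name) file.path(config$outdir, name)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest(manifest, out("manifest.json"), config$outdir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  # --- input stage: a dissimilarity matrix, with or without a graph -------
  g <- NULL; D <- NULL
  if (!is.null(config$dissimilarity_csv)) {
    D <- stage("input", check_dissimilarity(read_matrix_csv(config$dissimilarity_csv)))
  } else if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    cfg <- stage("input", sample_points(sy$model, sy$n, sy$dim %||% 2L,
                                        sy$params %||% list(),
                                        seed = derive_seed(config$seed, 1L)))
    if (!is.null(sy$threshold)) {
      g <- geometric_graph(cfg, sy$threshold)
    } else {
      D <- planted_dissimilarity(cfg)
    }
  } else {
    g <- stage("input", build_graph(parse_sif(config$sif), config$allowed_types))
  }

  K <- NULL
  if (!is.null(g)) {
    if (n_nodes(g) > 5000L) {
      stop("dense all-pairs pipeline is capped at 5000 nodes (got ",
           n_nodes(g), ")")
    }
    stage("network", {
      write_network_tables(g, out("edges.csv"), out("nodes.csv"))
    })
    K <- stage("spring_model", {
      m <- node_masses(g)
      if (any(m == 0)) {  # isolated nodes cannot carry springs
        keep <- which(m > 0)
        g <- induced_network(g, keep)
        m <- m[keep]
      }
      A <- oriented_incidence(g)
      C <- weighted_incidence(A, m)
      rescale_stiffness(stiffness_equilibrium(C, tol = config$tol))
    })
    D <- stiffness_to_dissimilarity(K)
    dimnames(D) <- list(g$node_ids, g$node_ids)
    write_matrix_csv(K$K_rescaled, out("stiffness_rescaled.csv"))
    write_matrix_csv(D, out("dissimilarity.csv"))
  }
  if (is.null(rownames(D))) {
    dimnames(D) <- list(sprintf("n%04d", seq_len(nrow(D))),
                        sprintf("n%04d", seq_len(nrow(D))))
  }

  tab <- stage("geometry_selection",
               select_geometry(D, dims = config$dims, models = config$models,
                               kappa = config$kappa, refine = config$refine))
  utils::write.csv(as.data.frame(tab), out("stress_table.csv"),
                   row.names = FALSE)
  best_model <- attr(tab, "best_model")
  best_dim <- attr(tab, "best_dimension")
  best <- attr(tab, "embeddings")[[paste0(best_model, "_", best_dim)]]
  jsonlite::write_json(list(best_model = best_model, best_dimension = best_dim,
                            stress = best$stress),
                       out("selection.json"), auto_unbox = TRUE, digits = NA)
  coords <- data.frame(node_id = rownames(D), best$coordinates)
  names(coords) <- c("node_id", paste0("x", seq_len(best_dim)))
  if (!is.null(best$radial)) coords$radial <- best$radial
  utils::write.csv(coords, out("coordinates.csv"), row.names = FALSE)

  if (best_model == "hyperbolic") {
    rc <- stage("radial_clustering", {
      r <- radial_coordinates(best)
      kmx <- min(config$k_max, length(unique(r)) - 1L, length(r) - 1L)
      k <- as.integer(elbow_k(r, k_max = kmx, restarts = 10L,
                              seed = derive_seed(config$seed, 2L)))
      cl <- kmeans_radial(r, k, restarts = config$restarts,
                          seed = derive_seed(config$seed, 3L))
      st <- stability_analysis(r, k, runs = config$stability_runs,
                               seed = derive_seed(config$seed, 4L))
      utils::write.csv(data.frame(node_id = rownames(D), radial = r,
                                  cluster = cl$assignment),
                       out("clusters.csv"), row.names = FALSE)
      utils::write.csv(data.frame(run = seq_len(st$runs),
                                  wss = st$wss_distribution,
                                  bss = st$bss_distribution),
                       out("stability.csv"), row.names = FALSE)
      driver <- NULL
      if (!is.null(K)) {
        dr <- driver_cluster(K, cl$assignment, min_pairs = config$min_pairs)
        utils::write.csv(dr$table, out("driver_report.csv"), row.names = FALSE)
        driver <- dr$driver_cluster_id
      }
      list(driver = driver,
           summary = list(k = k, wss = cl$wss, bss = cl$bss,
                          median_bss_wss = attr(st, "median_bss_wss")))
    })
    manifest$driver_cluster <- rc$driver
    manifest$clustering <- rc$summary
    if (!is.null(g)) {
      stage("spectral_baseline", {
        W <- adjacency_from_network(g)
        ke <- as.integer(eigengap_k(W, k_max = config$k_max))
        sb <- spectral_clustering(W, max(ke, 2L),
                                  seed = derive_seed(config$seed, 5L),
                                  restarts = config$restarts)
        jsonlite::write_json(list(k_eigengap = ke, sizes = sb$sizes,
                                  wss = sb$wss, bss = sb$bss,
                                  wss_by_cluster = sb$wss_by_cluster),
                             out("spectral.json"), digits = NA)
      })
    }
  } else {
    manifest$note <- paste0("best geometry is ", best_model,
                            "; radial clustering (hyperbolic-only) skipped")
  }
  manifest$best_model <- best_model
  manifest$best_dimension <- best_dim
  manifest <- write_manifest(manifest, out("manifest.json"), config$outdir)
  invisible(manifest)
}

write_manifest <- function(manifest, path, outdir) {
  files <- setdiff(list.files(outdir), "manifest.json")
  hashes <- tools::md5sum(file.path(outdir, files))
  manifest$files <- as.list(stats::setNames(unname(hashes), files))
  manifest$config_hash <- digest_config(manifest$config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(manifest)
}

digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# subgraph induced on a node-index subset (re-indexes edges)
induced_network <- function(g, keep) {
  sel <- g$edges[, 1L] %in% keep & g$edges[, 2L] %in% keep
  edges <- g$edges[sel, , drop = FALSE]
  edges[] <- match(edges, keep)
  new_gene_network(g$node_ids[keep], edges,
                   multi_edge_count = sum(sel),
                   self_loop_count = 0L)
}

#' Dense adjacency matrix of a gene network
#'
#' @param g A \code{gene_network}.
#' @return Symmetric 0/1 matrix with node-id dimnames.
#' @export
adjacency_from_network <- function(g) {
  n <- n_nodes(g)
  W <- matrix(0, n, n, dimnames = list(g$node_ids, g$node_ids))
  W[g$edges] <- 1
  W[g$edges[, c(2L, 1L), drop = FALSE]] <- 1
  W
}
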