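# Global topological metrics of binary undirected graphs, their
# normalisation against degree-preserving null models, and AUC summaries
# over the sparsity grid. Shortest paths, local clustering, local
# efficiency and degree-preserving rewiring are delegated to igraph; the
# conventions (low-degree nodes contribute 0, reachable-pair path length)
# are fixed here and verified against brute-force oracles in the tests.

as_graph <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency matrix must be square")
  igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                      diag = FALSE)
}

#' Mean clustering coefficient (Cp)
#'
#' Average over nodes of the local clustering coefficient
#' 2 t_i / (k_i (k_i - 1)), where t_i is the number of triangles through
#' node i and k_i its degree. Nodes with degree < 2 contribute 0.
#'
#' @param adj Symmetric 0/1 adjacency matrix, zero diagonal.
#' @return Scalar mean clustering coefficient.
#' @export
clustering_coefficient <- function(adj) {
  g <- as_graph(adj)
  mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
}

#' Characteristic path length (Lp)
#'
#' Mean shortest-path length over all reachable ordered pairs of distinct
#' nodes. Unreachable pairs are excluded with a warning; a graph with no
#' reachable pair at all (e.g. edgeless) is an error.
#'
#' @param adj Symmetric 0/1 adjacency matrix.
#' @return Scalar mean shortest-path length, in hops.
#' @export
characteristic_path_length <- function(adj) {
  d <- igraph::distances(as_graph(adj))
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  if (length(finite) == 0L)
    stop("characteristic path length undefined: no connected node pair")
  if (length(finite) < length(off))
    warning("graph is disconnected; path length averaged over reachable pairs")
  mean(finite)
}

#' Global efficiency (Eglobal)
#'
#' Mean inverse shortest-path length over all pairs of distinct nodes, with
#' 1/infinity = 0 for unreachable pairs, so disconnection is handled
#' natively.
#'
#' @param adj Symmetric 0/1 adjacency matrix.
#' @return Scalar in [0, 1].
#' @export
global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(0)
  d <- igraph::distances(as_graph(adj))
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency (Elocal)
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours (the node itself excluded). Nodes with fewer than two
#' neighbours contribute 0. This is the fault-tolerance measure whose AUC
#' over the sparsity grid is the headline predictor of the framework.
#'
#' @param adj Symmetric 0/1 adjacency matrix.
#' @return Scalar in [0, 1].
#' @export
local_efficiency <- function(adj) {
  adj <- as.matrix(adj) != 0
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2L) return(0)
    dense_efficiency(adj[nb, nb, drop = FALSE])
  }, 0))
}

# Global efficiency of a small dense 0/1 adjacency via BFS levels computed
# with boolean matrix products; distances stay inside the given (sub)graph.
dense_efficiency <- function(a) {
  m <- nrow(a)
  if (m < 2L) return(0)
  a <- a != 0
  d <- matrix(Inf, m, m)
  diag(d) <- 0
  d[a] <- 1
  reach <- a
  step <- 1L
  repeat {
    reach <- (reach %*% a) > 0
    step <- step + 1L
    new <- reach & is.infinite(d)
    if (!any(new) || step > m) break
    d[new] <- step
  }
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (m * (m - 1))
}

#' Node (nodal) efficiency
#'
#' E_i = (1/(n-1)) * sum_{j != i} 1/d_ij, a per-node centrality: the higher
#' a node's efficiency, the shorter its average route to the rest of the
#' network.
#'
#' @param adj Symmetric 0/1 adjacency matrix.
#' @return Numeric vector of length n.
#' @export
node_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- igraph::distances(as_graph(adj))
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' Degree-preserving random rewiring (Maslov-Sneppen null model)
#'
#' Produces a randomised graph with exactly the degree sequence of the
#' input via repeated double-edge swaps, the field-standard null model for
#' small-world normalisation. Uses the current R random stream; seed with
#' \code{set.seed()} for reproducibility.
#'
#' @param adj Symmetric 0/1 adjacency matrix.
#' @param n_rewires_per_edge Swap attempts per edge (default 10).
#' @return A rewired 0/1 adjacency matrix with the same degree sequence.
#' @export
rewire_null <- function(adj, n_rewires_per_edge = 10) {
  g <- as_graph(adj)
  m <- igraph::ecount(g)
  if (m < 2L) {
    warning("fewer than 2 edges; returning the graph unchanged")
    return(adj)
  }
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = n_rewires_per_edge * m))
  out <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  storage.mode(out) <- "double"
  dimnames(out) <- dimnames(adj)
  out
}

#' Small-world normalisation (gamma, lambda, sigma)
#'
#' Normalises clustering and path length by their means over an ensemble of
#' degree-matched null graphs: gamma = Cp / <Cp_null>, lambda =
#' Lp / <Lp_null>, sigma = gamma / lambda. sigma > 1 is the usual
#' small-world signature.
#'
#' @param adj Symmetric 0/1 adjacency matrix.
#' @param nulls List of null adjacency matrices (e.g. from
#'   \code{rewire_null}).
#' @return Named vector c(gamma, lambda, sigma).
#' @export
normalized_smallworld <- function(adj, nulls) {
  if (!is.list(nulls) || length(nulls) == 0L)
    stop("'nulls' must be a nonempty list of adjacency matrices")
  cp <- clustering_coefficient(adj)
  lp <- characteristic_path_length(adj)
  cp0 <- mean(vapply(nulls, clustering_coefficient, 0))
  lp0 <- mean(vapply(nulls, function(a)
    suppressWarnings(characteristic_path_length(a)), 0))
  if (cp0 == 0 || lp0 == 0)
    stop("null-ensemble mean of zero; normalisation undefined")
  g <- cp / cp0
  l <- lp / lp0
  c(gamma = g, lambda = l, sigma = g / l)
}

#' Trapezoidal area under a metric curve
#'
#' Integrates a topological metric over the sparsity grid by the composite
#' trapezoid rule, collapsing the curve to a single scalar feature per
#' subject and metric.
#'
#' @param y Metric values at the grid points.
#' @param x Strictly increasing grid (default \code{sparsity_grid()}).
#' @return Scalar AUC.
#' @export
auc_trapezoid <- function(y, x = sparsity_grid()) {
  if (length(x) < 2L) stop("AUC needs at least 2 grid points")
  if (length(y) != length(x)) stop("curve and grid lengths differ")
  if (any(diff(x) <= 0)) stop("grid must be strictly increasing")
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

all_metrics <- c("Eglobal", "Elocal", "Cp", "Lp", "gamma", "lambda", "sigma")

#' Metric curves and AUCs over the sparsity grid
#'
#' Binarizes a Fisher-Z connectivity matrix at every sparsity threshold of
#' the grid and evaluates the requested global topological metrics at each
#' threshold, attaching the trapezoidal AUC of every curve. The normalised
#' metrics (gamma, lambda, sigma) use a fresh degree-preserving null
#' ensemble at every grid point, seeded deterministically from \code{seed}.
#'
#' @param z Fisher-Z (or any weighted) connectivity matrix.
#' @param grid Strictly increasing sparsity thresholds in (0, 1].
#' @param metrics Subset of
#'   \code{c("Eglobal","Elocal","Cp","Lp","gamma","lambda","sigma")}.
#' @param null_n Null graphs per grid point for the normalised metrics
#'   (default 100).
#' @param null_rewires Swap attempts per edge in each null (default 10).
#' @param seed Integer seed for the null ensembles; NULL uses the current
#'   stream.
#' @param ranking Edge-ranking rule passed to \code{binarize_at_sparsity}.
#' @return Object of class \code{"metric_curves"}: list with \code{grid},
#'   \code{curves} (named list of per-grid vectors) and \code{aucs} (named
#'   scalar vector).
#' @export
metric_curves <- function(z, grid = sparsity_grid(), metrics = all_metrics,
                          null_n = 100, null_rewires = 10, seed = NULL,
                          ranking = "signed") {
  metrics <- match.arg(metrics, all_metrics, several.ok = TRUE)
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stop("grid must be strictly increasing with >= 2 points")
  if (any(grid <= 0 | grid > 1)) stop("grid values must lie in (0, 1]")
  need_null <- any(c("gamma", "lambda", "sigma") %in% metrics)
  if (need_null && null_n < 1L)
    stop("normalised metrics require null_n >= 1")
  curves <- lapply(stats::setNames(metrics, metrics),
                   function(m) numeric(length(grid)))
  for (k in seq_along(grid)) {
    adj <- binarize_at_sparsity(z, grid[k], ranking = ranking)
    vals <- tryCatch(
      eval_point_metrics(adj, metrics, null_n, null_rewires,
                         if (is.null(seed)) NULL
                         else derive_seed(seed, "null", k)),
      error = function(e) stop(sprintf("at sparsity %.2f: %s", grid[k],
                                       conditionMessage(e)), call. = FALSE))
    for (m in metrics) curves[[m]][k] <- vals[[m]]
  }
  structure(list(grid = grid, curves = curves,
                 aucs = vapply(curves, auc_trapezoid, 0, x = grid)),
            class = "metric_curves")
}

eval_point_metrics <- function(adj, metrics, null_n, null_rewires, seed) {
  out <- list()
  if ("Eglobal" %in% metrics) out$Eglobal <- global_efficiency(adj)
  if ("Elocal" %in% metrics) out$Elocal <- local_efficiency(adj)
  if (any(c("Cp", "gamma", "sigma") %in% metrics))
    out$Cp <- clustering_coefficient(adj)
  if (any(c("Lp", "lambda", "sigma") %in% metrics))
    out$Lp <- suppressWarnings(characteristic_path_length(adj))
  if (any(c("gamma", "lambda", "sigma") %in% metrics)) {
    nulls <- local_seed(seed, replicate(null_n,
      rewire_null(adj, null_rewires), simplify = FALSE))
    sw <- normalized_smallworld(adj, nulls)
    out$gamma <- unname(sw["gamma"])
    out$lambda <- unname(sw["lambda"])
    out$sigma <- unname(sw["sigma"])
  }
  out
}

#' @export
print.metric_curves <- function(x, ...) {
  cat(sprintf("Topological metric curves over %d sparsity thresholds [%.2f, %.2f]\n",
              length(x$grid), min(x$grid), max(x$grid)))
  cat("AUCs:\n")
  print(round(x$aucs, 4))
  invisible(x)
}
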