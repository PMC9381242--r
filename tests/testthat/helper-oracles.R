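# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately avoid the code paths they check:
# shortest paths by Floyd-Warshall, clustering by direct triangle
# enumeration, LSSVR by an explicitly assembled KKT system solved with
# qr.solve on a dist()-based kernel.

oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_floyd_warshall(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  mean(sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  }))
}

oracle_path_length <- function(adj) {
  d <- oracle_floyd_warshall(adj)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_node_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- oracle_floyd_warshall(adj)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  mean(sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / (k * (k - 1))   # twice the triangle count / k(k-1)
  }))
}

# Dense LSSVR oracle: same model, independently assembled and solved.
oracle_lssvr_predict <- function(x, y, J, sigma2, xq) {
  x <- as.matrix(x)
  xq <- as.matrix(xq)
  n <- nrow(x)
  K <- exp(-as.matrix(stats::dist(x))^2 / sigma2)
  M <- cbind(rbind(0, matrix(1, n, 1)),
             rbind(matrix(1, 1, n), K + diag(n) / J))
  sol <- qr.solve(M, c(0, y))
  kq <- t(apply(xq, 1, function(q)
    exp(-colSums((t(x) - q)^2) / sigma2)))
  drop(kq %*% sol[-1]) + sol[1]
}

random_adjacency <- function(n, p) {
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  adj + t(adj)
}

ring_lattice <- function(n, k) {
  adj <- matrix(0, n, n)
  for (d in seq_len(k)) {
    i <- seq_len(n)
    j <- ((i + d - 1) %% n) + 1
    adj[cbind(i, j)] <- 1
    adj[cbind(j, i)] <- 1
  }
  adj
}

# A small, fast cohort configuration for unit tests.
tiny_config <- function(seed = 42, ...) {
  cohort_config(n_patients = 6, n_controls = 6, n_rois = 30,
                n_timepoints = 60, module_size = 10, seed = seed, ...)
}
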