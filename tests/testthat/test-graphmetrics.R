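triangle <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
star4 <- rbind(c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0))
path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
k4_minus_edge <- local({
  a <- 1 - diag(4)
  a[1, 2] <- a[2, 1] <- 0
  a
})

test_that("clustering coefficient matches hand enumeration on canonical graphs", {
  expect_equal(clustering_coefficient(triangle), 1)
  expect_equal(clustering_coefficient(star4), 0)
  # per-node values 2/3, 2/3, 1, 1
  expect_equal(clustering_coefficient(k4_minus_edge), 5 / 6)
})

test_that("path length and efficiencies match hand-computed distances", {
  k5 <- 1 - diag(5)
  expect_equal(characteristic_path_length(k5), 1)
  expect_equal(characteristic_path_length(path3), 4 / 3)
  expect_error(characteristic_path_length(matrix(0, 2, 2)), "no connected")
  expect_equal(global_efficiency(k5), 1)
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)
  expect_equal(local_efficiency(triangle), 1)
  expect_equal(local_efficiency(star4), 0)
  expect_equal(node_efficiency(star4)[1], 1)
  expect_equal(node_efficiency(path3)[1], 0.75)
  expect_equal(node_efficiency(rbind(c(0, 0), c(0, 0)))[1], 0)
})

test_that("all distance-based metrics agree with Floyd-Warshall brute force on random graphs", {
  set.seed(11)
  for (r in 1:50) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n, runif(1, 0.25, 0.9))
    if (sum(adj) == 0) next
    expect_equal(global_efficiency(adj), oracle_global_efficiency(adj),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(adj), oracle_local_efficiency(adj),
                 tolerance = 1e-12)
    expect_equal(node_efficiency(adj), oracle_node_efficiency(adj),
                 tolerance = 1e-12)
    expect_equal(clustering_coefficient(adj), oracle_clustering(adj),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(characteristic_path_length(adj)),
                 oracle_path_length(adj), tolerance = 1e-12)
  }
})

test_that("degree-preserving rewiring conserves the degree sequence and mixes edges", {
  set.seed(21)
  adj <- random_adjacency(100, 0.1)
  null <- rewire_null(adj, 10)
  expect_equal(rowSums(null), rowSums(adj))
  expect_equal(sum(null), sum(adj))
  expect_lt(sum(null * adj), sum(adj))  # some edges moved
  expect_warning(rewire_null(path3 * 0, 10), "fewer than 2")
  # a triangle admits no legal double-edge swap
  expect_equal(rewire_null(triangle, 10), triangle)
})

test_that("small-world normalisation is self-consistent and detects lattice clustering", {
  adj <- random_adjacency(30, 0.3)
  sw <- normalized_smallworld(adj, list(adj))
  expect_equal(unname(sw), c(1, 1, 1))
  set.seed(31)
  lat <- ring_lattice(40, 3)
  nulls <- replicate(20, rewire_null(lat, 10), simplify = FALSE)
  sw <- normalized_smallworld(lat, nulls)
  expect_gt(sw["gamma"], 1)
  expect_equal(unname(sw["sigma"]), unname(sw["gamma"] / sw["lambda"]),
               tolerance = 1e-12)
  expect_error(normalized_smallworld(adj, list()), "nonempty")
})

test_that("trapezoidal AUC is exact for constant and linear curves", {
  g <- sparsity_grid()
  expect_equal(auc_trapezoid(rep(2.5, 31), g), 0.3 * 2.5, tolerance = 1e-12)
  expect_equal(auc_trapezoid(g, g), 0.075, tolerance = 1e-12)
  expect_error(auc_trapezoid(1, 0.1), "2 grid points")
  expect_error(auc_trapezoid(1:3, c(0.1, 0.3, 0.2)), "increasing")
  expect_error(auc_trapezoid(1:3, c(0.1, 0.2)), "lengths")
})

test_that("metric curves cover the grid, are seeded-deterministic, and Eglobal is nondecreasing", {
  set.seed(41)
  ts <- generate_subject_timeseries("control", tiny_config(), seed = 5)
  z <- fisher_z(correlation_matrix(ts))
  mc <- suppressWarnings(metric_curves(z, metrics = c("Eglobal", "Elocal", "Cp"),
                                       null_n = 0))
  expect_length(mc$curves$Eglobal, 31)
  expect_true(all(diff(mc$curves$Eglobal) >= 0))
  expect_equal(unname(mc$aucs["Eglobal"]),
               auc_trapezoid(mc$curves$Eglobal, mc$grid))
  # normalised metrics with a seeded null ensemble are reproducible
  small_grid <- c(0.2, 0.3)
  m1 <- suppressWarnings(metric_curves(z, grid = small_grid, null_n = 3,
                                       seed = 7))
  m2 <- suppressWarnings(metric_curves(z, grid = small_grid, null_n = 3,
                                       seed = 7))
  expect_identical(m1$curves, m2$curves)
  expect_named(m1$curves, c("Eglobal", "Elocal", "Cp", "Lp",
                            "gamma", "lambda", "sigma"))
  expect_equal(m1$curves$sigma, m1$curves$gamma / m1$curves$lambda,
               tolerance = 1e-12)
  expect_error(metric_curves(z, grid = c(0.3, 0.2)), "increasing")
  expect_error(metric_curves(z, metrics = "gamma", null_n = 0), "null_n")
})
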