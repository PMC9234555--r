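# DCCM, correlation-weighted networks, centralities.

two_atom_traj <- function(dispA, dispB) {
  top <- topology(c("CA", "CA"), 1:2, c("ALA", "ALA"))
  z <- numeric(length(dispA))
  trajectory(top, cbind(dispA, z, z, dispB[, 1], dispB[, 2], z))
}

test_that("DCCM analytic limits: same phase 1, opposite -1, orthogonal 0", {
  ph <- sin(seq(0, 6 * pi, length.out = 200))
  same <- two_atom_traj(ph, cbind(ph, 0 * ph))
  expect_equal(compute_dccm(same, "all", fit = FALSE)[1, 2], 1,
               tolerance = 1e-10)
  opp <- two_atom_traj(ph, cbind(-ph, 0 * ph))
  expect_equal(compute_dccm(opp, "all", fit = FALSE)[1, 2], -1,
               tolerance = 1e-10)
  orth <- two_atom_traj(ph, cbind(0 * ph, ph))
  expect_equal(abs(compute_dccm(orth, "all", fit = FALSE)[1, 2]), 0,
               tolerance = 1e-10)
})

test_that("DCCM diagonal is exactly 1 and values stay within [-1, 1]", {
  set.seed(61)
  tr <- random_ca_trajectory(8, 30)
  C <- compute_dccm(tr, "all")
  expect_equal(unname(diag(C)), rep(1, 8))
  expect_true(all(C >= -1 & C <= 1))
  expect_equal(unclass(C), t(unclass(C)))
})

test_that("DCCM matches the brute-force double-loop oracle", {
  set.seed(62)
  tr <- random_ca_trajectory(5, 10)
  C <- compute_dccm(tr, "all", fit = FALSE)
  expect_lt(max(abs(unclass(C) - oracle_dccm(tr$xyz))), 1e-10)
})

test_that("DCCM agrees with the independent bio3d implementation", {
  set.seed(63)
  tr <- random_ca_trajectory(6, 25)
  C <- compute_dccm(tr, "all", fit = FALSE)
  ref <- bio3d::dccm(tr$xyz)
  expect_lt(max(abs(unclass(C) - unclass(ref))), 1e-8)
})

test_that("covariance-block DCCM equals the direct computation", {
  set.seed(64)
  tr <- random_ca_trajectory(6, 40)
  ed <- essential_dynamics(tr, "all", fit = FALSE)
  expect_lt(max(abs(dccm_from_covariance(ed) -
                    compute_dccm(tr, "all", fit = FALSE))), 1e-8)
  # identity covariance -> identity DCCM; rank-1 same-direction -> all ones
  fake <- list(covariance = diag(6), topology = data.frame(residue_id = 1:2))
  expect_equal(unclass(dccm_from_covariance(fake)), diag(2),
               ignore_attr = TRUE)
  v <- rep(c(1, 0, 0), 2)
  fake2 <- list(covariance = outer(v, v), topology = data.frame(residue_id = 1:2))
  expect_equal(unclass(dccm_from_covariance(fake2)),
               matrix(1, 2, 2), ignore_attr = TRUE)
})

test_that("planted block correlations are recovered within 0.05 over 10 seeds", {
  worst <- 0
  for (s in 1:10) {
    g <- generate_gaussian_trajectory(n_residues = 20, rho_within = 0.8,
                                      n_frames = 10000, seed = 200 + s)
    C <- compute_dccm(g$traj, "all", fit = FALSE)
    worst <- max(worst, max(abs(unclass(C) - g$correlation)))
  }
  expect_lt(worst, 0.05)
})

test_that("network weights follow -ln|C| with thresholded edge inclusion", {
  C <- matrix(c(1, 1, 0.5, 0.2,
                1, 1, 0.5, 0.2,
                0.5, 0.5, 1, 0,
                0.2, 0.2, 0, 1), 4, byrow = TRUE)
  class(C) <- c("dccm", "matrix")
  net <- build_network(C, cmin = 0.3)
  e <- net$edges
  w12 <- e$weight[e$i == 1 & e$j == 2]
  expect_equal(w12, 0)                       # |C| = 1 -> omega = 0
  w13 <- e$weight[e$i == 1 & e$j == 3]
  expect_equal(w13, log(2), tolerance = 1e-12)   # natural-log convention
  expect_false(any(e$i == 1 & e$j == 4))     # |C| = 0.2 below cmin
  expect_false(any(e$i == 3 & e$j == 4))     # |C| = 0 always excluded
  # monotonicity: larger |C| gives strictly smaller weight
  cs <- c(0.31, 0.5, 0.7, 0.9, 1)
  ws <- -log(cs)
  expect_true(all(diff(ws) < 0))
})

test_that("degree centrality counts included edges per the adjacency rule", {
  path <- resnet_from_edges(3, data.frame(i = c(1, 2), j = c(2, 3),
                                          weight = c(1, 1)))
  expect_equal(degree_centrality(path), c(1L, 2L, 1L))
  iso <- resnet_from_edges(3, data.frame(i = 1, j = 2, weight = 1))
  expect_equal(degree_centrality(iso)[3], 0L)
  k4 <- resnet_from_edges(4, expand.grid(i = 1:4, j = 1:4) |>
                            subset(i < j) |> transform(weight = 1))
  expect_equal(degree_centrality(k4), rep(3L, 4))
})

test_that("closeness centrality matches hand enumeration and the complete graph", {
  path <- resnet_from_edges(3, data.frame(i = c(1, 2), j = c(2, 3),
                                          weight = c(1, 1)))
  expect_equal(closeness_centrality(path), c(2 / 3, 1, 2 / 3))
  k4 <- resnet_from_edges(4, expand.grid(i = 1:4, j = 1:4) |>
                            subset(i < j) |> transform(weight = 1))
  expect_equal(closeness_centrality(k4), rep(1, 4))
})

test_that("betweenness matches exhaustive enumeration on canonical graphs", {
  path <- resnet_from_edges(3, data.frame(i = c(1, 2), j = c(2, 3),
                                          weight = c(1, 1)))
  expect_equal(betweenness_centrality(path), c(0, 1 / 3, 0))
  ring <- resnet_from_edges(4, data.frame(i = c(1, 2, 3, 4),
                                          j = c(2, 3, 4, 1), weight = 1))
  expect_equal(betweenness_centrality(ring), rep(1 / 12, 4),
               tolerance = 1e-12)
})

test_that("centralities match the exhaustive-path oracle on 30 random graphs", {
  set.seed(65)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    edges <- random_graph(n)
    net <- resnet_from_edges(n, edges)
    got_b <- betweenness_centrality(net)
    exp_b <- oracle_betweenness(edges, n)
    expect_lt(max(abs(got_b - exp_b)), 1e-10)
    got_c <- closeness_centrality(net)
    exp_c <- oracle_closeness(edges, n)
    expect_lt(max(abs(got_c - exp_c)), 1e-10)
    # sum rule against the oracle's total
    expect_equal(sum(got_b), sum(exp_b), tolerance = 1e-10)
  }
})

test_that("centralities agree with igraph on weighted graphs", {
  skip_if_not_installed("igraph")
  set.seed(66)
  for (rep in 1:5) {
    n <- 8
    edges <- random_graph(n, extra = 10)
    net <- resnet_from_edges(n, edges)
    ig <- igraph::graph_from_data_frame(
      data.frame(from = edges$i, to = edges$j), directed = FALSE,
      vertices = data.frame(name = 1:n))
    ib <- igraph::betweenness(ig, weights = edges$weight, directed = FALSE)
    expect_equal(betweenness_centrality(net) * n * (n - 1) / 2,
                 unname(ib), tolerance = 1e-8)
    ic <- igraph::closeness(ig, weights = edges$weight)
    expect_equal(closeness_centrality(net), unname(ic) * (n - 1),
                 tolerance = 1e-8)
  }
})

test_that("centralities are equivariant under node relabeling", {
  set.seed(67)
  n <- 7
  edges <- random_graph(n)
  net <- resnet_from_edges(n, edges)
  perm <- sample(n)
  pedges <- data.frame(i = perm[edges$i], j = perm[edges$j],
                       weight = edges$weight)
  pnet <- resnet_from_edges(n, pedges)
  expect_equal(betweenness_centrality(pnet)[perm],
               betweenness_centrality(net), tolerance = 1e-12)
  expect_equal(closeness_centrality(pnet)[perm],
               closeness_centrality(net), tolerance = 1e-12)
  expect_equal(degree_centrality(pnet)[perm], degree_centrality(net))
})

test_that("contact filtering prunes long-range edges", {
  g <- generate_gaussian_trajectory(n_residues = 15, rho_within = 0.9,
                                    n_frames = 500, seed = 68)
  C <- compute_dccm(g$traj, "all", fit = FALSE)
  co <- frame_coords(g$traj, 1)
  net_all <- build_network(C, cmin = 0.3)
  net_flt <- build_network(C, cmin = 0.3, contact_coords = co,
                           contact_cutoff = 6)
  expect_lt(nrow(net_flt$edges), nrow(net_all$edges))
  d <- as.matrix(dist(co))
  expect_true(all(d[cbind(net_flt$edges$i, net_flt$edges$j)] <= 6))
})

test_that("centrality differences and absolute selections threshold correctly", {
  prof <- function(b) {
    out <- data.frame(residue_id = 1:5, degree = 1:5,
                      closeness = seq(0.2, 1, 0.2), betweenness = b)
    class(out) <- c("centrality_profile", "data.frame")
    out
  }
  a <- prof(c(0.05, 0.2, 0.1, 0.3, 0))
  expect_identical(centrality_difference(a, a)$selected$residue_id,
                   integer(0))
  b <- prof(c(0.05, 0.4, 0.1, 0.3, 0))
  d <- centrality_difference(a, b, threshold = 0.12)
  expect_equal(d$selected$residue_id, 2L)
  expect_equal(nrow(centrality_difference(a, b, threshold = 0)$selected), 5)
  expect_equal(high_centrality(a, 0.15)$residue_id, c(2L, 4L))
  bad <- prof(rep(0, 5)); bad$residue_id <- 2:6
  expect_error(centrality_difference(a, bad), "different residue sets")
})

test_that("centrality Pearson matrix behaves at its analytic limits", {
  prof <- data.frame(residue_id = 1:100, degree = 1:100,
                     closeness = (1:100) * 2, betweenness = -(1:100))
  class(prof) <- c("centrality_profile", "data.frame")
  r <- centrality_pearson(prof)
  expect_equal(r["degree", "closeness"], 1)
  expect_equal(r["degree", "betweenness"], -1)
  set.seed(69)
  ind <- data.frame(residue_id = 1:1000, degree = rnorm(1000),
                    closeness = rnorm(1000), betweenness = rnorm(1000))
  class(ind) <- c("centrality_profile", "data.frame")
  expect_lt(max(abs(centrality_pearson(ind)[upper.tri(diag(3))])), 0.1)
})
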