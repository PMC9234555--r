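# RMSD / Rg / RMSF series and their distributions.

ca_traj <- function(xyz_list) {
  n <- nrow(xyz_list[[1]])
  top <- topology(rep("CA", n), seq_len(n), rep("ALA", n))
  trajectory(top, do.call(rbind, lapply(xyz_list, function(m) as.vector(t(m)))))
}

test_that("rmsd is zero on repeats, analytic under translation, zero after fit", {
  set.seed(1)
  ref <- helix_backbone(8)
  tr <- ca_traj(rep(list(ref), 5))
  expect_equal(rmsd_series(tr, 1L, "all", fit = TRUE)$values, rep(0, 5),
               tolerance = 1e-10)
  shifted <- sweep(ref, 2, c(1, 1, 1), FUN = "+")
  tr2 <- ca_traj(list(ref, shifted))
  expect_equal(rmsd_series(tr2, 1L, "all", fit = FALSE)$values[2], sqrt(3),
               tolerance = 1e-12)
  expect_lt(rmsd_series(tr2, 1L, "all", fit = TRUE)$values[2], 1e-10)
})

test_that("radius of gyration matches analytic values", {
  two <- ca_traj(list(rbind(c(0, 0, 0), c(2, 0, 0))))
  expect_equal(rg_series(two, "all", mass_weighted = FALSE)$values, 1.0)
  one_top <- topology("CA", 1L, "ALA")
  one <- trajectory(one_top, matrix(c(3, 4, 5), 1))
  expect_equal(rg_series(one, "all")$values, 0)
  square <- ca_traj(list(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))))
  expect_equal(rg_series(square, "all", mass_weighted = FALSE)$values, sqrt(2))
})

test_that("rg is invariant under global rotation and translation", {
  set.seed(3)
  base <- helix_backbone(10)
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- sweep(base %*% R, 2, c(10, -3, 2), FUN = "+")
  tr <- ca_traj(list(base, moved))
  vals <- rg_series(tr, "all")$values
  expect_equal(vals[1], vals[2], tolerance = 1e-10)
})

test_that("rmsf reproduces static, alternating, and Gaussian sampling laws", {
  ref <- helix_backbone(5)
  static <- ca_traj(rep(list(ref), 4))
  expect_equal(rmsf_per_residue(static, "all")$rmsf, rep(0, 5),
               tolerance = 1e-10)
  # one atom alternating +/- 1 A about its mean -> RMSF exactly 1
  a <- ref; b <- ref
  a[3, 1] <- a[3, 1] + 1; b[3, 1] <- b[3, 1] - 1
  alt <- ca_traj(list(a, b, a, b))
  expect_equal(rmsf_per_residue(alt, "all", fit = FALSE)$rmsf[3], 1.0)
  # isotropic Gaussian displacements: RMSF -> sigma * sqrt(3)
  set.seed(8)
  sigma <- 0.5
  nf <- 20000
  xyz <- matrix(rep(as.vector(t(ref)), each = nf), nf) +
    matrix(rnorm(nf * 15, sd = sigma), nf)
  tr <- trajectory(topology(rep("CA", 5), 1:5, rep("ALA", 5)), xyz)
  got <- rmsf_per_residue(tr, "all", fit = FALSE)$rmsf
  expect_equal(got, rep(sigma * sqrt(3), 5), tolerance = 0.02 / (sigma * sqrt(3)))
  expect_error(rmsf_per_residue(subset_trajectory(static, "all", frames = 1)),
               "2 frames")
})

test_that("rmsf ranks residues by planted variance", {
  set.seed(12)
  n <- 20; nf <- 10000
  sig <- seq(0.2, 2, length.out = n)
  g <- generate_gaussian_trajectory(n_residues = n, rho_within = 0,
                                    sigma = sig, n_frames = nf, seed = 5)
  got <- rmsf_per_residue(g$traj, "all", fit = FALSE)$rmsf
  expect_gt(cor(got, sig, method = "spearman"), 0.9)
})

test_that("distributions integrate to one and recover planted modes", {
  set.seed(21)
  mix <- c(rnorm(25000, 3.7, 0.2), rnorm(25000, 7.1, 0.3))
  d <- metric_distribution(mix, n_bins = 100)
  expect_equal(sum(d$probability) * d$bin_width, 1, tolerance = 1e-9)
  expect_equal(nrow(d$peaks), 2)
  expect_equal(sort(d$peaks$location), c(3.7, 7.1), tolerance = 0.1 / 3.7)
  single <- rnorm(20000, 4.5, 0.3)
  d1 <- metric_distribution(single, n_bins = 100)
  expect_equal(nrow(d1$peaks), 1)
  expect_equal(d1$peaks$location, 4.5, tolerance = 0.1 / 4.5)
})

test_that("uniform samples yield no peaks; constant series yields one bin", {
  set.seed(22)
  # sampling noise per bin must sit well below the 5% prominence floor
  u <- metric_distribution(runif(200000), n_bins = 20)
  expect_equal(nrow(u$peaks), 0)
  k <- metric_distribution(rep(2.5, 500), n_bins = 10)
  expect_equal(length(k$bin_centers), 1)
  expect_equal(nrow(k$peaks), 1)
  expect_equal(k$peaks$location, 2.5)
})

test_that("two-state rmsd mean converges to the occupancy-weighted mixture mean", {
  ts <- generate_two_state(n_residues = 40, n_frames = 6000,
                           transition_prob = 0.05, seed = 31)
  r <- rmsd_series(ts$traj, reference = ts$reference, selection = "all",
                   fit = FALSE)
  occ <- tabulate(ts$labels, 2) / length(ts$labels)
  # per-state rmsd means include the isotropic noise floor
  state_means <- vapply(1:2, function(s)
    mean(r$values[ts$labels == s]), numeric(1))
  expected <- sum(occ * state_means)
  se <- sd(r$values) / sqrt(length(r$values))
  expect_lt(abs(mean(r$values) - expected), 2 * se + 1e-9)
  # and the planted separation dominates: bimodal about 3.7 / 7.14
  expect_equal(sort(state_means), sort(ts$centers), tolerance = 0.05)
})
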