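# Covariance analysis, projections, cosine content, porcupine vectors.

test_that("single-atom two-point covariance is analytic", {
  top <- topology("CA", 1L, "ALA")
  tr <- trajectory(top, rbind(c(1, 0, 0), c(-1, 0, 0)))
  ed <- essential_dynamics(tr, "all", fit = FALSE)
  expect_equal(ed$covariance[1, 1], 1)
  expect_equal(sum(abs(ed$covariance)) - ed$covariance[1, 1], 0)
})

test_that("covariance matches the brute-force ensemble-average oracle", {
  set.seed(42)
  tr <- random_ca_trajectory(5, 10)
  ed <- essential_dynamics(tr, "all", fit = FALSE)
  expect_lt(max(abs(ed$covariance - oracle_covariance(tr$xyz))), 1e-10)
  # and with fitting: oracle applied to the identically fitted coordinates
  edf <- essential_dynamics(tr, "all", fit = TRUE)
  expect_equal(sum(edf$eigenvalues), sum(diag(edf$covariance)),
               tolerance = 1e-10)
})

test_that("sample covariance converges to the planted covariance", {
  g <- generate_gaussian_trajectory(n_residues = 5, rho_within = 0.8,
                                    n_frames = 50000, seed = 17)
  ed <- essential_dynamics(g$traj, "all", fit = FALSE)
  err <- max(abs(ed$covariance - g$covariance))
  expect_lt(err, 0.05 * max(g$covariance))
})

test_that("eigendecomposition is orthonormal, PSD and reconstructs the covariance", {
  set.seed(43)
  tr <- random_ca_trajectory(6, 40)
  ed <- essential_dynamics(tr, "all")
  V <- ed$eigenvectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  expect_gt(min(ed$eigenvalues), -1e-8 * max(ed$eigenvalues))
  rec <- V %*% diag(ed$eigenvalues) %*% t(V)
  expect_lt(max(abs(ed$covariance - rec)), 1e-8 * max(abs(ed$covariance)))
})

test_that("variance fractions are cumulative shares of the spectrum", {
  fake <- structure(list(eigenvalues = c(8, 1, 1)),
                    class = "essential_dynamics")
  expect_equal(variance_fraction(fake, 2), 0.9)
  iso <- structure(list(eigenvalues = rep(2, 6)),
                   class = "essential_dynamics")
  expect_equal(variance_fraction(iso, 1), 1 / 6)
  rank1 <- structure(list(eigenvalues = c(5, 0, 0)),
                     class = "essential_dynamics")
  expect_equal(variance_fraction(rank1, 1), 1)
  expect_equal(variance_fraction(fake, 3), 1)
})

test_that("projection variance equals the eigenvalue; static projections vanish", {
  set.seed(44)
  tr <- random_ca_trajectory(5, 200)
  ed <- essential_dynamics(tr, "all", fit = FALSE)
  total <- 0
  for (k in c(1, 2, 5)) {
    p <- project_trajectory(tr, ed, k)
    expect_lt(abs(mean(p$values)), 1e-6)
    expect_equal(mean(p$values^2), ed$eigenvalues[k],
                 tolerance = 1e-8)
  }
  all_var <- sum(vapply(seq_along(ed$eigenvalues), function(k)
    mean(project_trajectory(tr, ed, k)$values^2), numeric(1)))
  expect_equal(all_var, sum(diag(ed$covariance)), tolerance = 1e-6)
  static <- trajectory(tr$topology,
                       matrix(rep(tr$xyz[1, ], each = 4), 4),
                       times = 1:4)
  edp <- essential_dynamics(static, "all", fit = FALSE)
  ps <- project_trajectory(static, edp, 1)
  expect_lt(max(abs(ps$values)), 1e-10)
})

test_that("a planted dominant mode is recovered by PC1", {
  set.seed(45)
  n <- 20
  v <- rnorm(3 * n); v <- v / sqrt(sum(v^2))
  amp <- rnorm(20000, sd = 3)
  mu <- as.vector(t(helix_backbone(n)))
  xyz <- sweep(outer(amp, v), 2, mu, FUN = "+") +
    matrix(rnorm(20000 * 3 * n, sd = 0.1), 20000)
  tr <- trajectory(topology(rep("CA", n), 1:n, rep("ALA", n)), xyz)
  ed <- essential_dynamics(tr, "all", fit = FALSE)
  expect_gte(abs(sum(ed$eigenvectors[, 1] * v)), 0.99)
})

test_that("the top PC separates two planted conformational states", {
  ts <- generate_two_state(n_residues = 30, n_frames = 4000,
                           transition_prob = 0.05, seed = 46)
  ed <- essential_dynamics(ts$traj, "all", fit = FALSE)
  p <- project_trajectory(ts$traj, ed, 1)
  pred <- ifelse(p$values > 0, 1L, 2L)
  acc <- max(mean(pred == ts$labels), mean(3L - pred == ts$labels))
  expect_gte(acc, 0.95)
})

test_that("cosine content matches the quadrature oracle on analytic signals", {
  n <- 1000
  tt <- seq(0, 1, length.out = n)
  expect_equal(cosine_content(cos(pi * tt)), 1, tolerance = 1e-3)
  funs <- list(function(t) sin(pi * t),
               function(t) sin(2 * pi * t),
               function(t) cos(pi * t) + 0.3 * sin(3 * pi * t),
               function(t) t - 0.5)
  for (f in funs)
    expect_equal(cosine_content(f(tt)), oracle_cosine_content(f),
                 tolerance = 1e-2)
  # the mode orthogonal to the half-cosine scores near zero
  expect_lt(cosine_content(sin(pi * tt)), 0.05)
})

test_that("white-noise projections rarely exceed the cosine threshold", {
  hits <- vapply(1:100, function(s) {
    p <- drifting_mode_series(amplitude = 0, noise = 1, n = 10000, seed = s)
    cosine_content(p) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("select_pcs returns the lowest-index converged components or errors", {
  n <- 2000
  tt <- seq(0, 1, length.out = n)
  drift <- cos(pi * tt)              # content ~1: unconverged
  osc <- sin(6 * pi * tt)            # content ~0: converged
  both_pass <- cbind(osc, sin(8 * pi * tt), drift)
  expect_equal(select_pcs(NULL, both_pass), c(1L, 2L))
  one_passes <- cbind(osc, drift, drift)
  expect_equal(select_pcs(NULL, one_passes, n_select = 1L), 1L)
  expect_error(select_pcs(NULL, one_passes, n_select = 2L), "not converged")
  none <- cbind(drift, drift)
  expect_error(select_pcs(NULL, none), "not converged")
})

test_that("porcupine vectors scale, reshape and cap as documented", {
  set.seed(47)
  tr <- random_ca_trajectory(6, 50)
  ed <- essential_dynamics(tr, "all")
  pv <- porcupine_vectors(ed, 1, scale = 2)
  expect_equal(sum(pv$magnitude^2), 4, tolerance = 1e-10)
  expect_equal(nrow(pv), 6)
  z <- porcupine_vectors(ed, 1, scale = 0)
  expect_true(all(z$magnitude == 0))
  capped <- porcupine_vectors(ed, 1, scale = 100, cap = 5)
  expect_lte(max(capped$magnitude), 5)
  expect_equal(capped$magnitude,
               sqrt(capped$dx^2 + capped$dy^2 + capped$dz^2))
})
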