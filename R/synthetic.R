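# Seeded synthetic-trajectory generators with planted statistical structure.
#
# These stand in for long explicit-solvent MD trajectories when validating
# the analysis layers: Gaussian trajectories with planted block covariance
# (correlated "domains"), two-state hopping trajectories with bimodal RMSD,
# atomistic interaction fixtures with exact geometry, and drifting
# low-frequency scalar modes for cosine-content checks.  Every generator is
# a pure function of its arguments plus `seed`.

# Run expr with a local RNG state so generators do not disturb the caller's.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Coarse helical mean structure
#'
#' C-alpha positions on a helix-like curve (rise 1.5 A, ~100 degrees twist
#' per residue, radius 2.3 A) so that superposition is never degenerate.
#'
#' @param n_residues number of residues.
#' @param rise,twist_deg,radius helix parameters.
#' @return An `n x 3` coordinate matrix (Angstrom).
#' @export
helix_backbone <- function(n_residues, rise = 1.5, twist_deg = 100,
                           radius = 2.3) {
  k <- seq_len(n_residues) - 1
  th <- k * twist_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * k)
}

.ca_topology <- function(n_residues, resname = "ALA") {
  topology(rep("CA", n_residues), seq_len(n_residues),
           rep(resname, n_residues))
}

#' Gaussian trajectory with planted block covariance
#'
#' Residue displacements are multivariate normal about a helical mean, with
#' correlation `rho_within` between residues of the same block (domain) and
#' `rho_between` otherwise, applied identically and independently to the x,
#' y and z axes; per-site amplitude `sigma` (A).  The implied cross-
#' correlation matrix therefore equals the block-structured residue
#' correlation matrix.
#'
#' @param n_residues number of C-alpha sites.
#' @param blocks list of integer vectors partitioning (a subset of)
#'   `1:n_residues` into correlated domains; default: two equal halves.
#' @param rho_within,rho_between planted correlations (defaults 0.8 and 0).
#' @param sigma per-site displacement amplitude in Angstrom, scalar or
#'   per-residue vector (default 1).
#' @param n_frames number of frames.
#' @param seed RNG seed (output is a pure function of arguments + seed).
#' @return A list: `traj` (`"trajectory"`), `correlation` (planted residue
#'   correlation matrix), `covariance` (planted 3N x 3N covariance).
#' @export
generate_gaussian_trajectory <- function(n_residues = 40, blocks = NULL,
                                         rho_within = 0.8, rho_between = 0,
                                         sigma = 1, n_frames = 1000,
                                         seed = 1) {
  if (is.null(blocks)) {
    h <- floor(n_residues / 2)
    blocks <- list(seq_len(h), (h + 1):n_residues)
  }
  R <- matrix(rho_between, n_residues, n_residues)
  for (b in blocks) R[b, b] <- rho_within
  diag(R) <- 1
  sig <- rep_len(sigma, n_residues)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("planted correlation matrix is not PSD")
  L <- chol(R + diag(1e-10, n_residues))
  mu <- helix_backbone(n_residues)
  xyz <- .with_seed(seed, {
    out <- matrix(0, n_frames, 3 * n_residues)
    for (ax in 1:3) {
      Z <- matrix(stats::rnorm(n_frames * n_residues), n_frames)
      disp <- (Z %*% L) * rep(sig, each = n_frames)
      out[, seq(ax, 3 * n_residues, 3)] <-
        sweep(disp, 2, mu[, ax], FUN = "+")
    }
    out
  })
  Sigma <- (diag(sig) %*% R %*% diag(sig))
  cov3 <- matrix(0, 3 * n_residues, 3 * n_residues)
  for (ax in 1:3) {
    ix <- seq(ax, 3 * n_residues, 3)
    cov3[ix, ix] <- Sigma
  }
  list(traj = trajectory(.ca_topology(n_residues), xyz),
       correlation = R, covariance = cov3)
}

#' Two-state hopping trajectory with bimodal RMSD
#'
#' A hidden two-state Markov chain switches between two planted structures
#' built from a common reference: state structures displace a "mobile
#' domain" (the second half of the chain) so that their unfitted C-alpha
#' RMSDs to the reference equal `centers` (default 3.7 and 7.14 A, the
#' signature of a closed-to-open conformational transition).  Isotropic
#' Gaussian noise of width `sigma` is added per atom and frame.
#'
#' @param n_residues number of C-alpha sites.
#' @param centers planted RMSD-to-reference of the two states (A).
#' @param transition_prob per-frame probability of switching state.
#' @param sigma per-atom noise width (A).
#' @param n_frames number of frames.
#' @param start_state initial state (1 or 2).
#' @param seed RNG seed.
#' @return A list: `traj`, `labels` (integer state per frame), `reference`
#'   (`n x 3` reference coordinates), `centers` (the planted RMSD values),
#'   `state_structures` (list of two `n x 3` matrices), and `rg_centers`
#'   (radius of gyration of each noiseless state structure).
#' @export
generate_two_state <- function(n_residues = 60, centers = c(3.7, 7.14),
                               transition_prob = 0.02, sigma = 0.25,
                               n_frames = 2000, start_state = 1L, seed = 1) {
  stopifnot(length(centers) == 2, transition_prob >= 0, transition_prob < 1)
  ref <- helix_backbone(n_residues)
  mobile <- (floor(n_residues / 2) + 1):n_residues
  k <- length(mobile)
  # displacing k of n atoms by d gives unfitted RMSD d * sqrt(k / n)
  states <- lapply(centers, function(ctr) {
    d <- ctr * sqrt(n_residues / k)
    s <- ref
    s[mobile, 1] <- s[mobile, 1] + d
    s
  })
  top <- .ca_topology(n_residues)
  out <- .with_seed(seed, {
    labels <- integer(n_frames)
    st <- as.integer(start_state)
    flips <- stats::runif(n_frames) < transition_prob
    for (f in seq_len(n_frames)) {
      if (f > 1 && flips[f]) st <- 3L - st
      labels[f] <- st
    }
    noise <- matrix(stats::rnorm(n_frames * 3 * n_residues, sd = sigma),
                    n_frames)
    xyz <- t(vapply(seq_len(n_frames),
                    function(f) as.vector(t(states[[labels[f]]])),
                    numeric(3 * n_residues)))
    list(labels = labels, xyz = xyz + noise)
  })
  rg0 <- vapply(states, function(s) {
    ctr <- colMeans(s)
    sqrt(mean(rowSums(sweep(s, 2, ctr)^2)))
  }, numeric(1))
  list(traj = trajectory(top, out$xyz), labels = out$labels,
       reference = ref, centers = centers,
       state_structures = states, rg_centers = rg0)
}

#' Atomistic hydrogen-bond fixture with exact geometry
#'
#' Two residues (a serine-like donor with OG-HG and a glutamate-like
#' acceptor with OE1) positioned so that each frame realises the requested
#' donor-acceptor distance and hydrogen-donor-acceptor angle exactly.
#' Carbon scaffold atoms keep the residues superposable but carry no
#' donor/acceptor role.
#'
#' @param da_distance per-frame donor-acceptor distance(s), Angstrom;
#'   recycled to `n_frames`.
#' @param hda_angle per-frame hydrogen-donor-acceptor angle(s), degrees.
#' @param n_frames number of frames (default: length of the longer input).
#' @param dh_length donor-hydrogen covalent distance (default 1.0 A).
#' @return A `"trajectory"` of 6 atoms / 2 residues.
#' @export
hbond_fixture <- function(da_distance = 3.0, hda_angle = 0,
                          n_frames = max(length(da_distance),
                                         length(hda_angle)),
                          dh_length = 1.0) {
  d <- rep_len(da_distance, n_frames)
  a <- rep_len(hda_angle, n_frames)
  if (any(d <= 0)) stop("donor-acceptor distance must be positive")
  if (any(a < 0 | a > 180)) stop("angle must lie in [0, 180] degrees")
  if (dh_length <= 0) stop("donor-hydrogen length must be positive")
  top <- topology(
    atom_name   = c("CA", "CB", "OG", "HG", "CA", "OE1"),
    residue_id  = c(1L, 1L, 1L, 1L, 2L, 2L),
    residue_name = c("SER", "SER", "SER", "SER", "GLU", "GLU"))
  xyz <- t(vapply(seq_len(n_frames), function(f) {
    th <- a[f] * pi / 180
    coords <- rbind(
      c(-2.5, 0.5, 0),                                 # CA  (donor side)
      c(-1.4, 0, 0),                                   # CB
      c(0, 0, 0),                                      # OG  donor
      dh_length * c(cos(th), sin(th), 0),              # HG  at angle th
      c(d[f] + 1.3, 0.6, 0),                           # CA  (acceptor side)
      c(d[f], 0, 0))                                   # OE1 acceptor
    as.vector(t(coords))
  }, numeric(18)))
  trajectory(top, xyz)
}

#' Atomistic salt-bridge fixture
#'
#' An arginine-like basic residue (NH1/NH2) and an acidic partner -- a
#' glutamate (OE1/OE2) or a phosphoserine dialect (O1P/O2P/O3P) -- placed so
#' the minimum N-O distance equals the request in every frame.
#'
#' @param no_distance per-frame minimum N-O distance(s), Angstrom.
#' @param n_frames number of frames (default `length(no_distance)`).
#' @param acidic one of `"GLU"`, `"SEP"`, `"SP1"`, `"SP2"` choosing the
#'   acceptor naming dialect.
#' @return A `"trajectory"` of 2 residues.
#' @export
saltbridge_fixture <- function(no_distance = 3.0,
                               n_frames = length(no_distance),
                               acidic = c("GLU", "SEP", "SP1", "SP2")) {
  acidic <- match.arg(acidic)
  d <- rep_len(no_distance, n_frames)
  if (any(d <= 0)) stop("N-O distance must be positive")
  o_names <- if (acidic == "GLU") c("OE1", "OE2") else c("O1P", "O2P")
  top <- topology(
    atom_name    = c("CA", "NH1", "NH2", "CA", o_names),
    residue_id   = c(1L, 1L, 1L, 2L, 2L, 2L),
    residue_name = c("ARG", "ARG", "ARG", acidic, acidic, acidic))
  xyz <- t(vapply(seq_len(n_frames), function(f) {
    coords <- rbind(
      c(-2.0, 1.2, 0),          # CA basic
      c(0, 0, 0),               # NH1 (closest nitrogen)
      c(-0.8, -1.0, 0.6),       # NH2
      c(d[f] + 2.0, 1.2, 0),    # CA acidic
      c(d[f], 0, 0),            # closest oxygen
      c(d[f] + 1.1, -0.8, 0.4)) # second oxygen, farther by construction
    as.vector(t(coords))
  }, numeric(18)))
  trajectory(top, xyz)
}

#' Drifting low-frequency scalar mode
#'
#' `amplitude * cos(pi * t/T * period_fraction) + Gaussian noise`, on
#' `t/T in [0, 1]` -- the signature of unconverged, diffusion-like sampling
#' used to exercise cosine-content screening.
#'
#' @param amplitude cosine amplitude.
#' @param period_fraction number of half-periods over the series (default 1).
#' @param noise Gaussian noise standard deviation.
#' @param n series length.
#' @param seed RNG seed.
#' @return Numeric vector of length `n`.
#' @export
drifting_mode_series <- function(amplitude = 1, period_fraction = 1,
                                 noise = 0, n = 1000, seed = 1) {
  tt <- seq(0, 1, length.out = n)
  base <- amplitude * cos(pi * tt * period_fraction)
  if (noise > 0) base <- base + .with_seed(seed, stats::rnorm(n, sd = noise))
  base
}
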