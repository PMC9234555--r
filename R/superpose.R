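# Least-squares rigid-body superposition (Kabsch algorithm).

#' Kabsch least-squares superposition
#'
#' Rotates and translates `mobile` onto `reference` so that the (optionally
#' weighted) RMSD is minimal over all proper rigid transforms.  The rotation
#' is guaranteed proper (determinant +1); reflections are never applied.
#'
#' @param mobile,reference numeric `n x 3` coordinate matrices (Angstrom),
#'   `n >= 3`, with `reference` not collinear.
#' @param weights optional non-negative per-atom weights (default uniform;
#'   pass masses for mass-weighted fitting).
#' @return A list with elements `coords` (fitted mobile, `n x 3`), `rmsd`
#'   (Angstrom), `rotation` (3 x 3) and the two centroids.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("mobile and reference must be matching n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  sv_ref <- svd(Q * sqrt(w))$d
  if (sv_ref[2] < 1e-8 * max(sv_ref, 1e-12))
    stop("degenerate (collinear) reference geometry")
  H <- t(P * w) %*% Q
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- sweep(P %*% R, 2, cr, FUN = "+")
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(coords = fitted, rmsd = rmsd, rotation = R,
       centroid_mobile = cm, centroid_reference = cr)
}

#' Weighted RMSD without fitting
#'
#' @param a,b `n x 3` coordinate matrices.
#' @param weights optional per-atom weights.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(a))
  w <- weights / sum(weights)
  sqrt(sum(w * rowSums((as.matrix(a) - as.matrix(b))^2)))
}

# Fit every frame of an xyz matrix (frames x 3N) onto reference coords.
.fit_xyz <- function(xyz, ref, weights = NULL) {
  out <- xyz
  for (f in seq_len(nrow(xyz))) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    out[f, ] <- as.vector(t(kabsch_superpose(co, ref, weights)$coords))
  }
  out
}

# Iterative mean structure: fit to first frame, average, re-fit to the
# average (gmx covar/rmsf convention, 2 rounds).  Returns list(xyz, mean).
.fit_to_mean <- function(xyz, weights = NULL, rounds = 2) {
  ref <- matrix(xyz[1, ], ncol = 3, byrow = TRUE)
  for (r in seq_len(rounds)) {
    xyz <- .fit_xyz(xyz, ref, weights)
    ref <- matrix(colMeans(xyz), ncol = 3, byrow = TRUE)
  }
  list(xyz = .fit_xyz(xyz, ref, weights), mean = ref)
}
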