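# Essential dynamics: Cartesian covariance analysis of C-alpha motion.
#
# The covariance matrix is the ensemble average
#   Cov[i, j] = < (r_i - <r_i>) (r_j - <r_j>) >,   i, j over 3N coordinates,
# with denominator n_frames (ensemble-average definition, not n-1), computed
# on unit-weighted selected atoms after least-squares superposition onto the
# iteratively refined mean structure (2 passes, gmx covar convention).

#' Fit an essential-dynamics (Cartesian PCA) model
#'
#' @param traj a `"trajectory"` with at least 2 frames.
#' @param selection atom selection (default `"name CA"`).
#' @param fit superpose frames onto the iterative mean structure first
#'   (default `TRUE`); disable for pre-fitted or synthetic coordinates.
#' @return An object of class `"essential_dynamics"` with elements
#'   `mean_structure` (n x 3, A), `covariance` (3N x 3N, A^2),
#'   `eigenvalues` (descending, A^2), `eigenvectors` (3N x 3N, orthonormal
#'   columns), `n_frames`, `topology`, `selection`, `fit`.
#' @export
essential_dynamics <- function(traj, selection = "name CA", fit = TRUE) {
  sub <- subset_trajectory(traj, selection)
  if (n_frames(sub) < 2) stop("covariance needs at least 2 frames")
  if (fit) {
    ft <- .fit_to_mean(sub$xyz)
    xyz <- ft$xyz; mu <- ft$mean
  } else {
    xyz <- sub$xyz
    mu <- matrix(colMeans(xyz), ncol = 3, byrow = TRUE)
  }
  xc <- sweep(xyz, 2, colMeans(xyz))
  cv <- crossprod(xc) / nrow(xc)          # denominator n: ensemble average
  eg <- eigen(cv, symmetric = TRUE)
  ord <- order(eg$values, decreasing = TRUE)  # ties keep original order
  structure(list(mean_structure = mu, covariance = cv,
                 eigenvalues = eg$values[ord],
                 eigenvectors = eg$vectors[, ord, drop = FALSE],
                 n_frames = nrow(xyz), topology = sub$topology,
                 selection = selection, fit = fit),
            class = "essential_dynamics")
}

#' @export
print.essential_dynamics <- function(x, ...) {
  m <- length(x$eigenvalues)
  cat("Essential dynamics:", nrow(x$mean_structure), "atoms,",
      x$n_frames, "frames,", m, "modes\n")
  cat(sprintf("  top eigenvalues (A^2): %s\n",
              paste(sprintf("%.3f", utils::head(x$eigenvalues, 5)),
                    collapse = ", ")))
  cat(sprintf("  PC1 variance fraction: %.3f; PC1+PC2: %.3f\n",
              variance_fraction(x, 1), variance_fraction(x, 2)))
  invisible(x)
}

#' @export
summary.essential_dynamics <- function(object, n = 10, ...) {
  k <- seq_len(min(n, length(object$eigenvalues)))
  data.frame(mode = k, eigenvalue = object$eigenvalues[k],
             variance_fraction = vapply(k, function(i)
               variance_fraction(object, i), numeric(1)))
}

#' @export
plot.essential_dynamics <- function(x, n = 20, ...) {
  k <- seq_len(min(n, length(x$eigenvalues)))
  graphics::plot(k, x$eigenvalues[k], type = "b", xlab = "mode",
                 ylab = "eigenvalue (A^2)", ...)
}

#' Cumulative variance fraction of the leading modes
#'
#' @param model an `"essential_dynamics"` object.
#' @param k number of leading modes.
#' @return `sum(lambda[1:k]) / sum(lambda)`, in \[0, 1\].
#' @export
variance_fraction <- function(model, k) {
  lam <- model$eigenvalues
  if (k < 1 || k > length(lam)) stop("k out of range")
  sum(lam[seq_len(k)]) / sum(lam)
}

#' Project a trajectory onto a principal component
#'
#' Frames are superposed onto the model's mean structure (when the model was
#' built with `fit = TRUE`), mean-centred, and dotted with the chosen
#' eigenvector.
#'
#' @param traj a `"trajectory"` (typically the one the model was built from).
#' @param model an `"essential_dynamics"` object.
#' @param component PC index (1-based).
#' @return A `"projection_series"`: list of `times`, `values` (A),
#'   `component`.
#' @export
project_trajectory <- function(traj, model, component = 1L) {
  if (component < 1 || component > ncol(model$eigenvectors))
    stop("component out of range")
  sub <- subset_trajectory(traj, model$selection)
  xyz <- if (model$fit) .fit_xyz(sub$xyz, model$mean_structure) else sub$xyz
  xc <- sweep(xyz, 2, as.vector(t(model$mean_structure)))
  vals <- as.vector(xc %*% model$eigenvectors[, component])
  structure(list(times = sub$times, values = vals, component = component),
            class = "projection_series")
}

#' @export
print.projection_series <- function(x, ...) {
  cat(sprintf("PC%d projection: %d frames, variance %.4f A^2\n",
              x$component, length(x$values), stats::var(x$values)))
  invisible(x)
}

#' @export
as.data.frame.projection_series <- function(x, ...) {
  data.frame(time = x$times, projection = x$values)
}

#' Cosine content of a principal-component projection
#'
#' Half-cosine (first period) form used in essential-dynamics sampling
#' diagnostics: `c = (2/T) (int p(t) cos(pi t / T) dt)^2 / int p(t)^2 dt`,
#' evaluated by discrete sums.  A value near 1 indicates random-diffusion-
#' like, unconverged sampling; converged internal modes score near 0.
#'
#' @param projection a `"projection_series"` or numeric vector, length >= 4.
#' @return Cosine content in \[0, 1\].
#' @export
cosine_content <- function(projection) {
  p <- if (inherits(projection, "projection_series")) projection$values
       else projection
  n <- length(p)
  if (n < 4) stop("need at least 4 points")
  if (all(p == 0)) stop("cosine content undefined for an all-zero projection")
  tt <- seq(0, 1, length.out = n)
  w <- c(0.5, rep(1, n - 2), 0.5) / (n - 1)   # trapezoidal quadrature, T = 1
  2 * sum(w * p * cos(pi * tt))^2 / sum(w * p^2)
}

#' Select principal components by cosine-content screening
#'
#' Returns the lowest-index PCs whose projection cosine content is at or
#' below `threshold`; the first two are conventionally labelled PC1/PC2 for
#' free-energy-landscape construction.
#'
#' @param model an `"essential_dynamics"` object.
#' @param projections a list of `"projection_series"`, or a numeric matrix
#'   with one column per PC (column k = projection onto PC k).
#' @param threshold cosine-content ceiling (default 0.1).
#' @param n_select how many passing PCs to return (default 2).
#' @return Integer vector of PC indices, length `n_select`.
#' @export
select_pcs <- function(model, projections, threshold = 0.1, n_select = 2L) {
  if (is.matrix(projections))
    projections <- lapply(seq_len(ncol(projections)),
                          function(k) projections[, k])
  cc <- vapply(projections, cosine_content, numeric(1))
  pass <- which(cc <= threshold)
  if (length(pass) < n_select)
    stop("only ", length(pass), " PC(s) have cosine content <= ", threshold,
         "; sampling is not converged - extend the trajectory")
  pass[seq_len(n_select)]
}

#' Porcupine displacement vectors for a mode
#'
#' Reshapes an eigenvector into one 3-vector per selected atom (per residue
#' for a C-alpha selection), scaled so that the summed squared magnitudes
#' equal `scale^2` for a unit eigenvector, with individual magnitudes capped
#' at `cap` (a display cutoff; 15 A suits whole-protein modes).
#'
#' @param model an `"essential_dynamics"` object.
#' @param component PC index.
#' @param scale overall amplitude in Angstrom (default 1).
#' @param cap per-vector magnitude cap in Angstrom (default 15).
#' @return A `data.frame`: `residue_id`, `dx`, `dy`, `dz`, `magnitude`.
#' @export
porcupine_vectors <- function(model, component = 1L, scale = 1, cap = 15) {
  v <- model$eigenvectors[, component]
  m <- matrix(v, ncol = 3, byrow = TRUE) * scale
  mag <- sqrt(rowSums(m^2))
  over <- mag > cap
  if (any(over)) m[over, ] <- m[over, ] * (cap / mag[over])
  mag <- pmin(mag, cap)
  data.frame(residue_id = model$topology$residue_id,
             dx = m[, 1], dy = m[, 2], dz = m[, 3], magnitude = mag)
}
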