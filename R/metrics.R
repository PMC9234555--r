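# Structural metrics: RMSD, radius of gyration, RMSF, distributions.

.metric_series <- function(times, values, metric, selection) {
  structure(list(times = times, values = values, metric = metric,
                 selection = selection), class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("%s series: %d frames, mean %.3f A, sd %.3f A (selection '%s')\n",
              x$metric, length(x$values), mean(x$values),
              stats::sd(x$values), x$selection))
  invisible(x)
}

#' @export
as.data.frame.metric_series <- function(x, ...) {
  data.frame(time = x$times, value = x$values)
}

#' @export
plot.metric_series <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time (ps)",
                 ylab = paste0(x$metric, " (A)"), ...)
}

#' @export
mean.metric_series <- function(x, ...) mean(x$values, ...)

#' RMSD time series
#'
#' Root-mean-square deviation of each frame from a reference structure, on a
#' selected atom set, optionally after Kabsch superposition ("fitted RMSD").
#'
#' @param traj a `"trajectory"` object.
#' @param reference reference frame index (default 1, the initial structure)
#'   or an `n x 3` coordinate matrix over the selected atoms.
#' @param selection atom selection (default `"name CA"`).
#' @param fit superpose each frame onto the reference first (default `TRUE`).
#' @param weights optional per-atom fitting weights (default uniform).
#' @return A `"metric_series"` (times in ps, values in Angstrom).
#' @export
rmsd_series <- function(traj, reference = 1L, selection = "name CA",
                        fit = TRUE, weights = NULL) {
  sub <- subset_trajectory(traj, selection)
  ref <- if (is.matrix(reference)) reference else frame_coords(sub, reference)
  if (nrow(ref) != n_atoms(sub))
    stop("reference atom count (", nrow(ref), ") does not match selection (",
         n_atoms(sub), ")")
  if (fit) {
    vals <- vapply(seq_len(n_frames(sub)), function(f)
      kabsch_superpose(frame_coords(sub, f), ref, weights)$rmsd, numeric(1))
  } else {
    w <- if (is.null(weights)) rep(1, nrow(ref)) else weights
    w3 <- rep(w / sum(w), each = 3)
    dev <- sweep(sub$xyz, 2, as.vector(t(ref)))
    vals <- sqrt(as.vector(dev^2 %*% w3))
  }
  .metric_series(sub$times, vals, "RMSD", selection)
}

#' Radius-of-gyration time series
#'
#' Per frame, `Rg^2 = sum(w_k |r_k - rbar|^2) / sum(w_k)` with `rbar` the
#' (weighted) centroid.  Mass-weighted by default (gmx gyrate behaviour);
#' set `mass_weighted = FALSE` for geometric Rg on C-alpha-only work.
#'
#' @param traj a `"trajectory"` object.
#' @param selection atom selection (default all atoms).
#' @param mass_weighted use atomic masses as weights (default `TRUE`).
#' @return A `"metric_series"` (Angstrom).
#' @export
rg_series <- function(traj, selection = "all", mass_weighted = TRUE) {
  sub <- subset_trajectory(traj, selection)
  w <- if (mass_weighted) sub$topology$mass else rep(1, n_atoms(sub))
  w <- w / sum(w)
  w3 <- rep(w, each = 3)
  # Rg^2 = sum_k w_k |r_k|^2 - |sum_k w_k r_k|^2 (parallel-axis form)
  second <- as.vector(sub$xyz^2 %*% w3)
  nA <- n_atoms(sub)
  ctr2 <- vapply(1:3, function(ax)
    as.vector(sub$xyz[, seq(ax, 3 * nA, 3), drop = FALSE] %*% w)^2,
    numeric(n_frames(sub)))
  if (is.null(dim(ctr2))) ctr2 <- matrix(ctr2, nrow = 1)
  vals <- sqrt(pmax(second - rowSums(ctr2), 0))
  .metric_series(sub$times, vals, "Rg", selection)
}

#' Per-residue RMSF
#'
#' Root-mean-square fluctuation of each residue about the time-average
#' structure, `RMSF_i = sqrt(<|r_i - <r_i>|^2>)`.  Frames are iteratively
#' superposed onto the average structure (two rounds, gmx rmsf convention)
#' unless `fit = FALSE`.  With a C-alpha selection the result is one value
#' per residue; broader selections are averaged within each residue.
#'
#' @param traj a `"trajectory"` object with at least 2 frames.
#' @param selection atom selection (default `"name CA"`).
#' @param fit superpose onto the iterative mean first (default `TRUE`).
#' @return A `data.frame` with columns `residue_id`, `residue_name`, `rmsf`
#'   (Angstrom).
#' @export
rmsf_per_residue <- function(traj, selection = "name CA", fit = TRUE) {
  sub <- subset_trajectory(traj, selection)
  if (n_frames(sub) < 2) stop("RMSF needs at least 2 frames")
  xyz <- if (fit) .fit_to_mean(sub$xyz)$xyz else sub$xyz
  mu <- colMeans(xyz)
  dev2 <- sweep(xyz, 2, mu)^2
  per_coord <- colMeans(dev2)                       # <dx^2> per coordinate
  per_atom <- sqrt(colSums(matrix(per_coord, nrow = 3)))
  agg <- tapply(per_atom, sub$topology$residue_id, mean)
  rid <- as.integer(names(agg))
  data.frame(residue_id = rid,
             residue_name = sub$topology$residue_name[
               match(rid, sub$topology$residue_id)],
             rmsf = as.numeric(agg))
}

# Peak prominence: height minus the higher of the two key saddles separating
# the peak from taller terrain (classical topographic definition).
.peak_prominence <- function(y) {
  n <- length(y)
  is_max <- which(vapply(seq_len(n), function(i) {
    l <- if (i > 1) y[i - 1] else -Inf
    r <- if (i < n) y[i + 1] else -Inf
    y[i] > l && y[i] >= r
  }, logical(1)))
  # prominence = height minus the higher of the two bounding saddles; a side
  # with no taller peak contributes its lowest valley down to the series edge
  prom <- vapply(is_max, function(i) {
    left <- y[seq_len(i - 1)]
    higher_l <- which(left > y[i])
    lsad <- if (length(higher_l)) min(y[(max(higher_l)):(i)]) else min(y[1:i])
    right <- if (i < n) y[(i + 1):n] else numeric(0)
    higher_r <- which(right > y[i])
    rsad <- if (length(higher_r)) min(y[i:(i + min(higher_r))]) else min(y[i:n])
    y[i] - max(lsad, rsad)
  }, numeric(1))
  list(index = is_max, prominence = prom)
}

#' Probability distribution of a metric series with mode detection
#'
#' Normalised histogram (`sum(probability) * bin_width == 1`) with peaks
#' reported as local maxima whose topographic prominence exceeds
#' `prominence` times the tallest bin.
#'
#' @param series a `"metric_series"` or numeric vector.
#' @param n_bins number of equal-width bins (default 100).
#' @param prominence minimum relative prominence for a peak (default 0.05).
#' @return A `"metric_distribution"` with `bin_centers`, `probability`
#'   (density), and `peaks` (`data.frame` of `location`, `height`).
#' @export
metric_distribution <- function(series, n_bins = 100, prominence = 0.05) {
  x <- if (inherits(series, "metric_series")) series$values else series
  if (length(x) < n_bins)
    stop("series length (", length(x), ") must be >= n_bins (", n_bins, ")")
  rng <- range(x)
  if (diff(rng) == 0) {                        # constant series: single bin
    return(structure(list(bin_centers = rng[1], probability = 1,
                          bin_width = 1,
                          peaks = data.frame(location = rng[1], height = 1)),
                     class = "metric_distribution"))
  }
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  prob <- h$density
  pk <- .peak_prominence(prob)
  keep <- pk$prominence >= prominence * max(prob)
  structure(list(bin_centers = h$mids, probability = prob,
                 bin_width = diff(br)[1],
                 peaks = data.frame(location = h$mids[pk$index[keep]],
                                    height = prob[pk$index[keep]])),
            class = "metric_distribution")
}

#' @export
print.metric_distribution <- function(x, ...) {
  cat("Distribution over", length(x$bin_centers), "bins;",
      nrow(x$peaks), "peak(s)")
  if (nrow(x$peaks))
    cat(" at", paste(sprintf("%.2f", x$peaks$location), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.metric_distribution <- function(x, ...) {
  data.frame(bin_center = x$bin_centers, probability = x$probability)
}

#' @export
plot.metric_distribution <- function(x, ...) {
  graphics::plot(x$bin_centers, x$probability, type = "h",
                 xlab = "value (A)", ylab = "probability density", ...)
  if (nrow(x$peaks))
    graphics::points(x$peaks$location, x$peaks$height, col = 2, pch = 19)
}
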