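# Two-dimensional free-energy landscapes from collective-variable pairs.
#
# G(bin) = -ln( P(bin) / P_max ) in units of kT, so the most populated bin
# sits at G = 0 and empty bins are masked.  Any pair of collective variables
# works; the classic choices are (RMSD, Rg) and (PC1, PC2).

#' Build a free-energy surface from two collective-variable series
#'
#' @param cv_x,cv_y equal-length numeric vectors or `"metric_series"` /
#'   `"projection_series"` objects, at least 100 points.
#' @param n_bins bins per axis (default 32).
#' @param temperature_K temperature label in Kelvin (default 300); G is in
#'   kT units, so this is metadata for converting to kJ/mol downstream.
#' @param xlab,ylab axis names for reporting.
#' @return An object of class `"fel"`: bin edges and centers, `G` matrix
#'   (kT; `NA` on empty bins), `counts`, `assignment` (per-frame bin index
#'   pair), the input CV vectors, and `temperature`.
#' @export
build_fel <- function(cv_x, cv_y, n_bins = 32, temperature_K = 300,
                      xlab = "CV1", ylab = "CV2") {
  x <- if (is.list(cv_x)) cv_x$values else cv_x
  y <- if (is.list(cv_y)) cv_y$values else cv_y
  if (length(x) != length(y)) stop("CV series lengths differ")
  if (length(x) < 100) stop("need at least 100 points for a landscape")
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  rx <- pad(range(x)); ry <- pad(range(y))
  bx <- seq(rx[1], rx[2], length.out = n_bins + 1)
  by <- seq(ry[1], ry[2], length.out = n_bins + 1)
  ix <- pmin(pmax(findInterval(x, bx, rightmost.closed = TRUE), 1L), n_bins)
  iy <- pmin(pmax(findInterval(y, by, rightmost.closed = TRUE), 1L), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  if (sum(counts > 0) == 1)
    warning("degenerate landscape: all points fall in a single bin")
  G <- matrix(NA_real_, n_bins, n_bins)
  pop <- counts > 0
  G[pop] <- -log(counts[pop] / max(counts))
  structure(list(x_edges = bx, y_edges = by,
                 x_centers = (bx[-1] + bx[-length(bx)]) / 2,
                 y_centers = (by[-1] + by[-length(by)]) / 2,
                 G = G, counts = counts,
                 assignment = cbind(ix, iy), cv_x = x, cv_y = y,
                 temperature = temperature_K, xlab = xlab, ylab = ylab),
            class = "fel")
}

#' @export
print.fel <- function(x, ...) {
  cat(sprintf("Free-energy surface %dx%d bins (%s vs %s), %d samples\n",
              nrow(x$G), ncol(x$G), x$xlab, x$ylab, length(x$cv_x)))
  cat(sprintf("  populated bins: %d; max G: %.2f kT (T = %g K)\n",
              sum(!is.na(x$G)), max(x$G, na.rm = TRUE), x$temperature))
  invisible(x)
}

#' @export
as.data.frame.fel <- function(x, ...) {
  grid <- expand.grid(ix = seq_along(x$x_centers), iy = seq_along(x$y_centers))
  data.frame(x = x$x_centers[grid$ix], y = x$y_centers[grid$iy],
             G = as.vector(x$G), populated = !is.na(as.vector(x$G)))
}

#' @export
plot.fel <- function(x, ...) {
  G <- x$G
  # display value for empty bins: 1 kT above the populated maximum
  G[is.na(G)] <- max(G, na.rm = TRUE) + 1
  graphics::image(x$x_centers, x$y_centers, G, xlab = x$xlab, ylab = x$ylab,
                  col = grDevices::hcl.colors(24, "viridis", rev = TRUE), ...)
}

# 8-connected neighbours of bin (i, j) on an n x m grid.
.neighbours8 <- function(i, j, n, m) {
  di <- rep(-1:1, times = 3); dj <- rep(-1:1, each = 3)
  keep <- !(di == 0 & dj == 0)
  ii <- i + di[keep]; jj <- j + dj[keep]
  ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= m
  cbind(ii[ok], jj[ok])
}

#' Identify free-energy basins
#'
#' Local minima of the surface with `G <= max_G` are found, every populated
#' bin at or below `max_G` is assigned to a minimum by steepest descent
#' (flood fill), and minima whose grid positions are within
#' `min_separation_bins` (Chebyshev distance) are merged into one basin.
#'
#' @param fes a `"fel"` object.
#' @param max_G basin ceiling in kT (default 3).
#' @param min_separation_bins merge minima closer than this many bins
#'   (default 2).
#' @return A list of basins, each a list with `label`, `bins` (two-column
#'   matrix of grid indices), `min_G`, `center` (CV coordinates of the
#'   minimum bin) and `n_frames`; ordered by increasing `min_G`.  Empty list
#'   when no bin lies below `max_G`.
#' @export
find_basins <- function(fes, max_G = 3, min_separation_bins = 2) {
  G <- fes$G
  n <- nrow(G); m <- ncol(G)
  elig <- which(!is.na(G) & G <= max_G, arr.ind = TRUE)
  if (!nrow(elig)) return(list())
  Gw <- G; Gw[is.na(Gw)] <- Inf
  # steepest-descent target of every eligible bin
  dest <- integer(nrow(elig))
  lin <- function(i, j) (j - 1L) * n + i
  elig_lin <- lin(elig[, 1], elig[, 2])
  for (k in seq_len(nrow(elig))) {
    i <- elig[k, 1]; j <- elig[k, 2]
    nb <- .neighbours8(i, j, n, m)
    vals <- Gw[cbind(nb[, 1], nb[, 2])]
    if (all(vals >= Gw[i, j])) dest[k] <- lin(i, j)   # plateau or minimum
    else { b <- which.min(vals); dest[k] <- lin(nb[b, 1], nb[b, 2]) }
  }
  # follow descent chains to their terminal minima
  root <- dest
  repeat {
    nxt <- root
    move <- match(root, elig_lin)
    ok <- !is.na(move)
    nxt[ok] <- dest[move[ok]]
    if (all(nxt == root)) break
    root <- nxt
  }
  # merge minima: (a) adjacent/close minima (plateaus), via union-find
  minima <- unique(root)
  parent <- seq_along(minima)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  mi <- ((minima - 1L) %% n) + 1L; mj <- ((minima - 1L) %/% n) + 1L
  for (a in seq_along(minima)) for (b in seq_len(a - 1L)) {
    if (max(abs(mi[a] - mi[b]), abs(mj[a] - mj[b])) <= min_separation_bins) {
      ra <- findp(a); rb <- findp(b)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  group <- vapply(seq_along(minima), findp, integer(1))
  basin_of <- group[match(root, minima)]
  out <- list()
  for (g in sort(unique(group))) {
    sel <- basin_of == g
    bins <- elig[sel, , drop = FALSE]
    gvals <- G[cbind(bins[, 1], bins[, 2])]
    bmin <- which.min(gvals)
    out[[length(out) + 1]] <- list(
      bins = bins, min_G = gvals[bmin],
      center = c(fes$x_centers[bins[bmin, 1]], fes$y_centers[bins[bmin, 2]]),
      n_frames = sum(fes$counts[cbind(bins[, 1], bins[, 2])]))
  }
  ord <- order(vapply(out, `[[`, numeric(1), "min_G"))
  out <- out[ord]
  for (k in seq_along(out)) out[[k]]$label <- k
  out
}

#' Representative frame of a basin
#'
#' The frame whose collective-variable pair is nearest (Euclidean distance
#' in z-scored CV space, standardised by the overall CV standard deviations)
#' to the basin's minimum bin center, among frames assigned to the basin.
#' Ties resolve to the earliest frame.
#'
#' @param fes a `"fel"` object.
#' @param basin one element of the [find_basins()] result.
#' @param traj optional `"trajectory"`; when given together with `path`, the
#'   frame is written as a PDB file.
#' @param path optional output PDB path.
#' @return The frame index (integer).
#' @export
representative_frame <- function(fes, basin, traj = NULL, path = NULL) {
  n <- nrow(fes$G)
  lin <- (basin$bins[, 2] - 1L) * n + basin$bins[, 1]
  frame_lin <- (fes$assignment[, 2] - 1L) * n + fes$assignment[, 1]
  members <- which(frame_lin %in% lin)
  if (!length(members)) stop("basin contains no frames")
  sx <- stats::sd(fes$cv_x); sy <- stats::sd(fes$cv_y)
  sx <- if (sx > 0) sx else 1; sy <- if (sy > 0) sy else 1
  d2 <- ((fes$cv_x[members] - basin$center[1]) / sx)^2 +
        ((fes$cv_y[members] - basin$center[2]) / sy)^2
  idx <- members[which.min(d2)]   # which.min takes the earliest tie
  if (!is.null(traj) && !is.null(path)) write_pdb(traj, path, frames = idx)
  idx
}

#' Free-energy difference between two basins
#'
#' @param basinA,basinB elements of a [find_basins()] result.
#' @return `min_G(B) - min_G(A)` in kT.
#' @export
basin_delta_g <- function(basinA, basinB) basinB$min_G - basinA$min_G
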