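# Dynamic cross-correlation and correlation-weighted residue networks.
#
# DCCM: C(i,j) = <dr_i . dr_j> / ( <dr_i^2>^1/2 <dr_j^2>^1/2 ) on C-alpha
# displacement vectors about their time means.  Network edges carry
# information-transfer weights w_ij = -ln|C_ij| (natural log); degree uses
# the binarised adjacency, closeness and betweenness use weighted shortest
# paths with exact tie multiplicity.

#' Dynamic cross-correlation matrix
#'
#' @param traj a `"trajectory"` with at least 2 frames.
#' @param selection atom selection, one atom per residue expected
#'   (default `"name CA"`).
#' @param fit superpose frames onto the iterative mean first (default
#'   `TRUE`; uses the same superposition as [essential_dynamics()]).
#' @return An `n x n` matrix of class `"dccm"` with `dimnames` set to
#'   residue ids; entries in \[-1, 1\], unit diagonal.  Residues with zero
#'   fluctuation give 0 off-diagonal entries (flagged by warning).
#' @export
compute_dccm <- function(traj, selection = "name CA", fit = TRUE) {
  sub <- subset_trajectory(traj, selection)
  if (n_frames(sub) < 2) stop("DCCM needs at least 2 frames")
  xyz <- if (fit) .fit_to_mean(sub$xyz)$xyz else sub$xyz
  xc <- sweep(xyz, 2, colMeans(xyz))
  n <- n_atoms(sub)
  xi <- xc[, seq(1, 3 * n, 3), drop = FALSE]
  yi <- xc[, seq(2, 3 * n, 3), drop = FALSE]
  zi <- xc[, seq(3, 3 * n, 3), drop = FALSE]
  num <- (crossprod(xi) + crossprod(yi) + crossprod(zi)) / nrow(xc)
  msf <- diag(num)
  zero <- msf <= 0
  if (any(zero))
    warning(sum(zero), " residue(s) with zero fluctuation; their ",
            "correlations are set to 0")
  denom <- sqrt(outer(pmax(msf, .Machine$double.eps),
                      pmax(msf, .Machine$double.eps)))
  C <- num / denom
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  rid <- sub$topology$residue_id
  dimnames(C) <- list(rid, rid)
  class(C) <- c("confdyn_dccm", "dccm", "matrix")
  C
}

#' DCCM from a fitted covariance model
#'
#' Builds the cross-correlation matrix from the 3x3 residue blocks of an
#' [essential_dynamics()] covariance:
#' `C(i,j) = tr(block_ij) / sqrt(tr(block_ii) tr(block_jj))`.  Agrees with
#' [compute_dccm()] on the same (identically fitted) trajectory.
#'
#' @param model an `"essential_dynamics"` object.
#' @return A `"dccm"` matrix.
#' @export
dccm_from_covariance <- function(model) {
  cv <- model$covariance
  n <- nrow(cv) / 3
  ix <- seq(1, 3 * n, 3)
  num <- cv[ix, ix] + cv[ix + 1, ix + 1] + cv[ix + 2, ix + 2]
  msf <- diag(num)
  denom <- sqrt(outer(pmax(msf, .Machine$double.eps),
                      pmax(msf, .Machine$double.eps)))
  C <- num / denom
  C[msf <= 0, ] <- 0; C[, msf <= 0] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  rid <- model$topology$residue_id
  dimnames(C) <- list(rid, rid)
  class(C) <- c("confdyn_dccm", "dccm", "matrix")
  C
}

#' @export
print.confdyn_dccm <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("DCCM: %d residues; mean |C| %.3f; %.1f%% of pairs |C| >= 0.5\n",
              nrow(x), mean(abs(off)), 100 * mean(abs(off) >= 0.5)))
  invisible(x)
}

#' @export
plot.confdyn_dccm <- function(x, ...) {
  graphics::image(seq_len(nrow(x)), seq_len(ncol(x)), unclass(x),
                  zlim = c(-1, 1), xlab = "residue", ylab = "residue",
                  col = grDevices::hcl.colors(25, "RdBu", rev = TRUE), ...)
}

#' Correlation-weighted residue interaction network
#'
#' Nodes are residues; an edge (i, j) is included when `|C_ij| >= cmin`
#' (and, if a contact filter is supplied, when the reference C-alpha
#' distance is within `contact_cutoff`).  Included edges carry weight
#' `w_ij = -ln |C_ij|` (zero-correlation pairs would have infinite weight
#' and are always excluded).
#'
#' @param dccm a `"dccm"` matrix.
#' @param cmin minimum `|C|` for an edge (default 0.3).
#' @param contact_coords optional `n x 3` reference C-alpha coordinates
#'   enabling the distance AND-filter.
#' @param contact_cutoff C-alpha contact cutoff in Angstrom (default 10).
#' @return An object of class `"resnet"`: `edges` data frame
#'   (`i`, `j`, `cij`, `weight`), `adjacency` logical matrix, `n` nodes,
#'   `residue_id`, and the parameters used.
#' @export
build_network <- function(dccm, cmin = 0.3, contact_coords = NULL,
                          contact_cutoff = 10) {
  n <- nrow(dccm)
  A <- abs(unclass(dccm)) >= cmin & abs(unclass(dccm)) > 0
  diag(A) <- FALSE
  if (!is.null(contact_coords)) {
    d <- as.matrix(stats::dist(contact_coords))
    A <- A & d <= contact_cutoff
  }
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      cij = dccm[idx],
                      weight = -log(abs(dccm[idx])))
  rid <- if (!is.null(rownames(dccm))) as.integer(rownames(dccm))
         else seq_len(n)
  structure(list(edges = edges, adjacency = A, n = n, residue_id = rid,
                 cmin = cmin,
                 contact_cutoff = if (is.null(contact_coords)) NA_real_
                                  else contact_cutoff),
            class = "resnet")
}

#' Construct a residue network directly from edge weights
#'
#' Mainly for testing and for importing externally defined graphs.
#'
#' @param n number of nodes.
#' @param edges data frame with columns `i`, `j`, `weight` (and optionally
#'   `cij`).
#' @return A `"resnet"` object.
#' @export
resnet_from_edges <- function(n, edges) {
  if (is.null(edges$cij)) edges$cij <- exp(-edges$weight)
  A <- matrix(FALSE, n, n)
  A[cbind(edges$i, edges$j)] <- TRUE
  A[cbind(edges$j, edges$i)] <- TRUE
  structure(list(edges = edges, adjacency = A, n = n,
                 residue_id = seq_len(n), cmin = NA_real_,
                 contact_cutoff = NA_real_),
            class = "resnet")
}

#' @export
print.resnet <- function(x, ...) {
  cat(sprintf("Residue network: %d nodes, %d edges (|C| >= %s)\n",
              x$n, nrow(x$edges),
              if (is.na(x$cmin)) "?" else format(x$cmin)))
  invisible(x)
}

# Weighted adjacency list: for each node, matrix of (neighbour, weight).
.adj_list <- function(net) {
  e <- net$edges
  out <- vector("list", net$n)
  for (k in seq_len(nrow(e))) {
    out[[e$i[k]]] <- rbind(out[[e$i[k]]], c(e$j[k], e$weight[k]))
    out[[e$j[k]]] <- rbind(out[[e$j[k]]], c(e$i[k], e$weight[k]))
  }
  out
}

# Dijkstra from source s; returns distances, path counts sigma, and the
# predecessor lists needed for Brandes accumulation.  Floating-point ties in
# path length are treated as equal within `tol`.
.dijkstra_full <- function(adj, n, s, tol = 1e-12) {
  dist <- rep(Inf, n); dist[s] <- 0
  sigma <- rep(0, n); sigma[s] <- 1
  preds <- vector("list", n)
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]; w <- nb[r, 2]
      alt <- dist[u] + w
      if (alt < dist[v] - tol) {
        dist[v] <- alt; sigma[v] <- sigma[u]; preds[[v]] <- u
      } else if (abs(alt - dist[v]) <= tol && !done[v] && v != s) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds)
}

#' Degree centrality
#'
#' Number of included edges per node: `C_d(i) = sum_j M_ij` with `M_ij = 1`
#' exactly when an edge with positive weight links i and j.
#'
#' @param net a `"resnet"` object.
#' @return Integer vector, one value per node.
#' @export
degree_centrality <- function(net) {
  as.integer(rowSums(net$adjacency))
}

#' Closeness centrality
#'
#' `C_c(i) = (N - 1) / sum_j d(i, j)` with `d` the weighted shortest-path
#' distance.  On a disconnected graph the sum runs over reachable nodes only
#' and the value is scaled by `(n_reach - 1) / (N - 1)` (Wasserman-Faust
#' correction); isolated nodes score 0.
#'
#' @param net a `"resnet"` object.
#' @return Numeric vector, one value per node.
#' @export
closeness_centrality <- function(net) {
  adj <- .adj_list(net)
  n <- net$n
  vapply(seq_len(n), function(i) {
    d <- .dijkstra_full(adj, n, i)$dist
    reach <- which(is.finite(d) & seq_len(n) != i)
    if (!length(reach)) return(0)
    ((length(reach))^2 / (n - 1)) / sum(d[reach])
  }, numeric(1))
}

#' Betweenness centrality
#'
#' `C_B(i) = 2 / (N (N - 1)) * sum_{a < b} tau_i^{ab} / N_ab`, where
#' `tau_i^{ab}` counts weighted shortest paths from a to b passing through i
#' (endpoints excluded) and `N_ab` is the total number of shortest paths.
#' Ties in path length are counted exactly (Brandes accumulation with a
#' 1e-12 comparison tolerance); disconnected pairs contribute 0.
#'
#' @param net a `"resnet"` object.
#' @return Numeric vector in \[0, 1\], one value per node.
#' @export
betweenness_centrality <- function(net) {
  adj <- .adj_list(net)
  n <- net$n
  cb <- rep(0, n)
  for (s in seq_len(n)) {
    sp <- .dijkstra_full(adj, n, s)
    ord <- order(sp$dist[is.finite(sp$dist)], decreasing = TRUE)
    nodes <- which(is.finite(sp$dist))[ord]
    delta <- rep(0, n)
    for (w in nodes) {
      for (v in sp$preds[[w]])
        delta[v] <- delta[v] + sp$sigma[v] / sp$sigma[w] * (1 + delta[w])
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  # the double loop over sources counts each unordered pair twice,
  # matching the 2/(N(N-1)) normalisation directly
  cb / (n * (n - 1))
}

#' All three centralities as a profile
#'
#' @param net a `"resnet"` object.
#' @return A `data.frame` of class `"centrality_profile"`: `residue_id`,
#'   `degree`, `closeness`, `betweenness`.
#' @export
centrality_profile <- function(net) {
  out <- data.frame(residue_id = net$residue_id,
                    degree = degree_centrality(net),
                    closeness = closeness_centrality(net),
                    betweenness = betweenness_centrality(net))
  class(out) <- c("centrality_profile", "data.frame")
  out
}

#' Residues above a centrality threshold
#'
#' @param profile a `"centrality_profile"`.
#' @param threshold minimum value (default 0.15).
#' @param measure column to threshold (default `"betweenness"`).
#' @return The subset of `profile` rows meeting the threshold.
#' @export
high_centrality <- function(profile, threshold = 0.15,
                            measure = "betweenness") {
  profile[profile[[measure]] >= threshold, , drop = FALSE]
}

#' Between-condition centrality difference
#'
#' @param profileA,profileB `"centrality_profile"` objects over the same
#'   residue set (e.g. wild-type vs phosphorylated).
#' @param threshold minimum `|delta|` to report a residue (default 0.12).
#' @param measure column to compare (default `"betweenness"`).
#' @return A list with `delta` (`data.frame` of `residue_id`, `delta`) and
#'   `selected` (rows with `|delta| >= threshold`).
#' @export
centrality_difference <- function(profileA, profileB, threshold = 0.12,
                                  measure = "betweenness") {
  if (!identical(profileA$residue_id, profileB$residue_id))
    stop("profiles cover different residue sets")
  delta <- data.frame(residue_id = profileA$residue_id,
                      delta = profileA[[measure]] - profileB[[measure]])
  list(delta = delta,
       selected = delta[abs(delta$delta) >= threshold, , drop = FALSE])
}

#' Pearson correlations among the three centrality measures
#'
#' @param profile a `"centrality_profile"`.
#' @return A 3 x 3 correlation matrix over degree, closeness, betweenness.
#' @export
centrality_pearson <- function(profile) {
  stats::cor(as.data.frame(profile)[c("degree", "closeness", "betweenness")])
}
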