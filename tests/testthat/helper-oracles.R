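# Independent oracles, deliberately naive: brute-force double loops and
# exhaustive path enumeration against which the package implementations are
# checked.

# Covariance by definition: Cov[i,j] = mean over frames of centred products.
oracle_covariance <- function(xyz) {
  n <- ncol(xyz)
  mu <- colMeans(xyz)
  cv <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    cv[i, j] <- mean((xyz[, i] - mu[i]) * (xyz[, j] - mu[j]))
  cv
}

# DCCM by definition, double loop over atom pairs and frames.
oracle_dccm <- function(xyz) {
  n <- ncol(xyz) / 3
  mu <- colMeans(xyz)
  C <- matrix(0, n, n)
  msf <- numeric(n)
  for (i in seq_len(n)) {
    ci <- 3 * (i - 1)
    msf[i] <- mean(rowSums(sweep(xyz[, ci + 1:3, drop = FALSE], 2,
                                 mu[ci + 1:3])^2))
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ci <- 3 * (i - 1); cj <- 3 * (j - 1)
    dots <- rowSums(sweep(xyz[, ci + 1:3, drop = FALSE], 2, mu[ci + 1:3]) *
                    sweep(xyz[, cj + 1:3, drop = FALSE], 2, mu[cj + 1:3]))
    C[i, j] <- mean(dots) / sqrt(msf[i] * msf[j])
  }
  C
}

# All simple paths between a and b (DFS); returns the minimal total weight,
# the number of tied shortest paths, and per-node pass-through counts.
oracle_shortest_paths <- function(edges, n, a, b, tol = 1e-9) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]; w <- edges$weight[k]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  best <- Inf; paths <- list()
  dfs <- function(node, visited, wsum, path) {
    if (node == b) {
      if (wsum < best - tol) { best <<- wsum; paths <<- list(path) }
      else if (abs(wsum - best) <= tol) paths[[length(paths) + 1]] <<- path
      return()
    }
    nb <- adj[[node]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      if (!visited[v] && wsum + nb[r, 2] <= best + tol) {
        visited[v] <- TRUE
        dfs(v, visited, wsum + nb[r, 2], c(path, v))
        visited[v] <- FALSE
      }
    }
  }
  vis <- rep(FALSE, n); vis[a] <- TRUE
  dfs(a, vis, 0, a)
  through <- integer(n)
  for (p in paths) {
    interior <- setdiff(p, c(a, b))
    through[interior] <- through[interior] + 1L
  }
  list(dist = best, n_paths = length(paths), through = through)
}

# Betweenness per the 2/(N(N-1)) * sum tau/N_ab definition, by enumeration.
oracle_betweenness <- function(edges, n) {
  cb <- numeric(n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    sp <- oracle_shortest_paths(edges, n, a, b)
    if (is.finite(sp$dist) && sp$n_paths > 0)
      cb <- cb + sp$through / sp$n_paths
  }
  2 * cb / (n * (n - 1))
}

# Closeness (N-1)/sum(d) from enumerated distances (connected graphs).
oracle_closeness <- function(edges, n) {
  vapply(seq_len(n), function(i) {
    d <- vapply(setdiff(seq_len(n), i), function(j)
      oracle_shortest_paths(edges, n, i, j)$dist, numeric(1))
    (n - 1) / sum(d)
  }, numeric(1))
}

# Random connected weighted graph on <= 8 nodes (spanning tree + extras).
random_graph <- function(n, extra = n) {
  perm <- sample(n)
  edges <- data.frame(i = perm[-1],
                      j = perm[vapply(2:n, function(k)
                        sample(k - 1, 1), integer(1))],
                      weight = stats::runif(n - 1, 0.2, 2))
  for (k in seq_len(extra)) {
    ij <- sample(n, 2)
    dup <- any((edges$i == ij[1] & edges$j == ij[2]) |
               (edges$i == ij[2] & edges$j == ij[1]))
    if (!dup) edges <- rbind(edges, data.frame(i = ij[1], j = ij[2],
                                               weight = stats::runif(1, 0.2, 2)))
  }
  edges
}

# Minimal RMSD over rotations by hierarchical grid search on Euler angles,
# refined to a 1e-3 rad grid.  Centres both structures first (the optimal
# translation aligns centroids).
oracle_min_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
    Rz2 <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3)
    Rz1 %*% Ry %*% Rz2
  }
  eval_rmsd <- function(a, b, c)
    sqrt(mean(rowSums((P %*% rot(a, b, c) - Q)^2)))
  best <- c(0, 0, 0); bval <- Inf
  step <- 0.3
  grid <- list(a = seq(0, 2 * pi, by = step),
               b = seq(0, pi, by = step),
               c = seq(0, 2 * pi, by = step))
  for (a in grid$a) for (b in grid$b) for (c in grid$c) {
    v <- eval_rmsd(a, b, c)
    if (v < bval) { bval <- v; best <- c(a, b, c) }
  }
  while (step > 1e-3) {
    step <- step / 5
    rng <- function(x) seq(x - 5 * step, x + 5 * step, by = step)
    for (a in rng(best[1])) for (b in rng(best[2])) for (c in rng(best[3])) {
      v <- eval_rmsd(a, b, c)
      if (v < bval) { bval <- v; best <- c(a, b, c) }
    }
  }
  bval
}

# Cosine content by adaptive quadrature on a continuous signal p(t), T = 1.
oracle_cosine_content <- function(pfun) {
  i1 <- stats::integrate(function(t) pfun(t) * cos(pi * t), 0, 1)$value
  i2 <- stats::integrate(function(t) pfun(t)^2, 0, 1)$value
  2 * i1^2 / i2
}

# Small C-alpha trajectory with Gaussian jitter, for oracle comparisons.
random_ca_trajectory <- function(n_atoms = 5, n_frames = 10, sd = 0.7) {
  top <- topology(rep("CA", n_atoms), seq_len(n_atoms), rep("ALA", n_atoms))
  mu <- helix_backbone(n_atoms)
  xyz <- matrix(rep(as.vector(t(mu)), each = n_frames), n_frames) +
    matrix(stats::rnorm(n_frames * 3 * n_atoms, sd = sd), n_frames)
  trajectory(top, xyz)
}
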