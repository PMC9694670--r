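# Independent oracles used by the tests. These deliberately re-derive the
# quantities with different algorithms than the package (dynamic programming
# and exhaustive enumeration instead of best-first propagation; long fixed-
# point iteration instead of the packaged convergence loop; explicit sign
# enumeration instead of the signed-rank distribution).

# Pairwise affinity matrix of a raster under the fuzzy-connectedness
# affinity, using the object statistics the package estimated.
affinity_matrix <- function(img, stats, w1 = 0.5, w2 = 0.5, adjacency = 8L) {
  nr <- nrow(img); nc <- ncol(img); n <- nr * nc
  W <- matrix(-Inf, n, n)
  diag(W) <- 1
  dirs <- if (adjacency == 4L) cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
          else cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  for (r in 1:nr) for (c in 1:nc) {
    i <- r + (c - 1) * nr
    for (k in seq_len(nrow(dirs))) {
      rr <- r + dirs[k, 1]; cc <- c + dirs[k, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      j <- rr + (cc - 1) * nr
      m <- (img[r, c] + img[rr, cc]) / 2
      g <- img[r, c] - img[rr, cc]
      W[i, j] <- w1 * exp(-(m - stats$mu_o)^2 / (2 * stats$sd_o^2)) +
                 w2 * exp(-g^2 / (2 * stats$sd_g^2))
    }
  }
  W
}

# Widest-path (max-min) connectivity by Floyd-Warshall dynamic programming.
fw_maxmin_conn <- function(W, seed_idx) {
  n <- nrow(W)
  for (k in seq_len(n)) {
    via <- outer(W[, k], W[k, ], pmin)
    W <- pmax(W, via)
  }
  conn <- W[seed_idx, ]
  conn[seed_idx] <- 1
  pmax(conn, 0)
}

# Max-min connectivity by exhaustive enumeration of all simple paths.
dfs_maxmin_conn <- function(W, seed_idx) {
  n <- nrow(W)
  best <- rep(0, n)
  best[seed_idx] <- 1
  visited <- rep(FALSE, n)
  recurse <- function(v, strength) {
    visited[v] <<- TRUE
    for (u in seq_len(n)) {
      if (visited[u] || !is.finite(W[v, u])) next
      s <- min(strength, W[v, u])
      if (s > best[u]) best[u] <<- s
      recurse(u, s)
    }
    visited[v] <<- FALSE
  }
  recurse(seed_idx, Inf)
  best
}

# Exhaustive threshold sweep for the area guard (no bisection).
sweep_area_oracle <- function(values, seed, target) {
  taus <- sort(unique(as.vector(values)), decreasing = TRUE)
  taus <- taus[taus <= values[seed[1], seed[2]]]
  areas <- vapply(taus, function(tau) {
    sum(kneeatlas:::seed_component_cpp(values, tau, seed[1], seed[2]))
  }, numeric(1))
  err <- abs(areas - target)
  best <- which(err == min(err))[1L]  # taus descending: first = largest tau
  list(threshold = taus[best], area = areas[best], all_areas = areas,
       taus = taus)
}

# Long plain fixed-point iteration for fuzzy c-means on a vector.
fcm_fixed_point <- function(x, c = 2, m = 2, centers0, iters = 2000) {
  v <- centers0
  for (it in seq_len(iters)) {
    d2 <- outer(x, v, function(a, b) (a - b)^2)
    d2 <- pmax(d2, 1e-300)
    w <- d2^(-1 / (m - 1))
    u <- w / rowSums(w)
    v <- colSums(u^m * x) / colSums(u^m)
  }
  list(centers = sort(v), memberships = u[, order(v)])
}

# Exact two-sided Wilcoxon signed-rank p-value by enumerating all 2^n sign
# assignments (no ties / zeros assumed).
wilcoxon_exact_enum <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}
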