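# Independent oracles used to cross-check the package implementations.
# Each is written from the defining property, not from the implementation
# it checks.

# Gabriel graph by the literal definition: edge (u,v) iff no third point
# lies in the closed ball with segment uv as diameter, tested via distance
# to the midpoint.
gabriel_bruteforce <- function(points) {
  points <- unique(as.matrix(points))
  p <- nrow(points)
  edges <- list()
  for (u in seq_len(p - 1)) {
    for (v in (u + 1):p) {
      mid <- (points[u, ] + points[v, ]) / 2
      rad2 <- sum((points[u, ] - points[v, ])^2) / 4
      dmid2 <- rowSums(sweep(points, 2, mid, "-")^2)
      blocked <- any(dmid2[-c(u, v)] <= rad2 + 1e-12)
      if (!blocked) edges[[length(edges) + 1]] <- c(u, v)
    }
  }
  do.call(rbind, edges)
}

# Kendall tau-b by exhaustive pair counting with tie correction.
kendall_bruteforce <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i])
      sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  nx <- n0 - sum(choose(table(x), 2))  # pairs not tied in x
  ny <- n0 - sum(choose(table(y), 2))
  (conc - disc) / sqrt(nx * ny)
}

# Exact quantile of the difference distribution b_i - a_j over all pairs
# (the population the bootstrap resamples from), inverse-ECDF convention.
exact_diff_quantile <- function(a, b, q) {
  diffs <- sort(as.vector(outer(b, a, "-")))
  diffs[ceiling(q * length(diffs))]
}

# Bayes boundary by dense grid search over the interval between the means.
bayes_boundary_grid <- function(pi, mu, sigma, n_grid = 2e6) {
  x <- seq(mu[1], mu[2], length.out = n_grid)
  f <- log(pi[1]) + dnorm(x, mu[1], sigma[1], log = TRUE) -
    log(pi[2]) - dnorm(x, mu[2], sigma[2], log = TRUE)
  i <- which(diff(sign(f)) != 0)[1]
  # linear interpolation across the sign change
  x[i] - f[i] * (x[i + 1] - x[i]) / (f[i + 1] - f[i])
}

# small two-blob dataset: well-separated classes in J dimensions
make_blobs <- function(n_per_class = 50, J = 3, sep = 10, seed = 1) {
  set.seed(seed)
  v <- rbind(matrix(rnorm(n_per_class * J, 0, 1), n_per_class, J),
             matrix(rnorm(n_per_class * J, sep, 1), n_per_class, J))
  tabular_dataset(v, rep(c("a", "b"), each = n_per_class))
}
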