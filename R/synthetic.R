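#' Two interlinked tori ("chainlink") benchmark dataset
#'
#' Three-dimensional two-class dataset of two orthogonally interlinked
#' rings: class 1 is sampled uniformly from the volume of a torus lying in
#' the xy-plane centered at the origin; class 2 from a torus in the
#' xz-plane whose center sits on the first ring's centerline (offset by the
#' major radius along x), so the rings interlock like chain links with the
#' maximum possible separation. The classes are not linearly separable,
#' which makes the dataset a classic stress test for structure-learning
#' methods.
#'
#' @param n_per_class points per class (default 500).
#' @param r_minor tube (minor) radius, default 0.1.
#' @param R_major centerline (major) radius, default 1.
#' @param seed integer seed.
#' @param surface if `TRUE`, sample from the torus surface instead of the
#'   volume (default `FALSE`: volume-uniform).
#' @return a [tabular_dataset] with columns X1, X2, X3 and classes 1 / 2.
#' @export
make_chainlink <- function(n_per_class = 500, r_minor = 0.1, R_major = 1,
                           seed = 42, surface = FALSE) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (r_minor >= R_major) stop("r_minor must be smaller than R_major (self-intersecting torus)")
  sample_torus <- function(n) {
    # angle along the centerline is uniform; the tube cross-section is
    # sampled by rejection so that density is uniform over the volume
    # (points farther from the torus axis occupy proportionally more volume)
    theta <- phi <- s <- numeric(0)
    while (length(theta) < n) {
      need <- n - length(theta)
      m <- ceiling(need * 1.6) + 8
      th <- stats::runif(m, 0, 2 * pi)
      ph <- stats::runif(m, 0, 2 * pi)
      ss <- if (surface) rep(r_minor, m) else r_minor * sqrt(stats::runif(m))
      acc <- stats::runif(m) < (R_major + ss * cos(ph)) / (R_major + r_minor)
      theta <- c(theta, th[acc])
      phi <- c(phi, ph[acc])
      s <- c(s, ss[acc])
    }
    cbind(theta = theta[1:n], phi = phi[1:n], s = s[1:n])
  }
  vals <- with_seed(seed, {
    t1 <- sample_torus(n_per_class)
    t2 <- sample_torus(n_per_class)
    # ring 1 in the xy-plane, centered at the origin
    p1 <- cbind((R_major + t1[, "s"] * cos(t1[, "phi"])) * cos(t1[, "theta"]),
                (R_major + t1[, "s"] * cos(t1[, "phi"])) * sin(t1[, "theta"]),
                t1[, "s"] * sin(t1[, "phi"]))
    # ring 2 in the xz-plane, centered at (R_major, 0, 0)
    p2 <- cbind(R_major + (R_major + t2[, "s"] * cos(t2[, "phi"])) * cos(t2[, "theta"]),
                t2[, "s"] * sin(t2[, "phi"]),
                (R_major + t2[, "s"] * cos(t2[, "phi"])) * sin(t2[, "theta"]))
    rbind(p1, p2)
  })
  colnames(vals) <- c("X1", "X2", "X3")
  tabular_dataset(vals, rep(c(1, 2), each = n_per_class))
}

#' Two-class dataset with systematically increasing class differences
#'
#' `n_v` variables, two classes with `n_per_class` observations each and
#' unit standard deviation throughout. Class means follow two linear ramps,
#' `mu_1i = 1 + (i - 1) (max1 - 1) / (n_v - 1)` and
#' `mu_2i = 1 + (i - 1) (max2 - 1) / (n_v - 1)`,
#' so the between-class mean difference grows linearly from 0 at the first
#' variable to `max1 - max2` at the last. Statistical significance of the
#' class difference therefore ascends systematically across variables --
#' a controlled ground truth for checking whether feature-importance
#' orderings survive augmentation.
#'
#' @param n_v number of variables (default 50).
#' @param n_per_class observations per class (default 10).
#' @param max1,max2 terminal class means (defaults 50 and 40).
#' @param seed integer seed.
#' @return a [tabular_dataset] of `2 * n_per_class` rows by `n_v` columns,
#'   classes 1 / 2.
#' @export
make_ascending_significance <- function(n_v = 50, n_per_class = 10,
                                        max1 = 50, max2 = 40, seed = 42) {
  if (n_v < 2) stop("n_v must be >= 2")
  i <- seq_len(n_v)
  mu1 <- 1 + (i - 1) * (max1 - 1) / (n_v - 1)
  mu2 <- 1 + (i - 1) * (max2 - 1) / (n_v - 1)
  vals <- with_seed(seed, {
    c1 <- sapply(mu1, function(m) stats::rnorm(n_per_class, m, 1))
    c2 <- sapply(mu2, function(m) stats::rnorm(n_per_class, m, 1))
    rbind(matrix(c1, n_per_class, n_v), matrix(c2, n_per_class, n_v))
  })
  colnames(vals) <- paste0("X", i)
  tabular_dataset(vals, rep(c(1, 2), each = n_per_class))
}

#' Two-class dataset with no class effect by construction
#'
#' Every variable is sampled for both classes from one and the same normal
#' distribution, with per-variable mean drawn from a discrete uniform on
#' the integers 10..30 and standard deviation from a discrete uniform on
#' 1..3 in steps of 0.01. To force the absence of even accidental group
#' differences, candidate variables are filtered by a two-sample t-test and
#' only those with `p >= p_min` (default 0.6) are kept; `n_v` of the
#' passing candidates are then sampled into the final table. The result is
#' a stringent null dataset: any variable later flagged as class-relevant
#' is a false positive.
#'
#' @param n_v number of variables retained (default 50).
#' @param n_per_class observations per class (default 10).
#' @param p_min minimum t-test p-value for inclusion (default 0.6).
#' @param seed integer seed.
#' @param max_batches candidate batches (of `4 * n_v` variables each) to
#'   try before giving up (default 50).
#' @return a [tabular_dataset] of `2 * n_per_class` rows by `n_v` columns,
#'   classes 1 / 2, with attribute `"filter_pvalues"` holding the t-test
#'   p-values of the retained variables.
#' @export
make_no_effect <- function(n_v = 50, n_per_class = 10, p_min = 0.6,
                           seed = 42, max_batches = 50) {
  if (n_v < 1) stop("n_v must be >= 1")
  if (p_min <= 0 || p_min >= 1) stop("p_min must be in (0, 1)")
  n <- n_per_class
  res <- with_seed(seed, {
    kept <- list()
    kept_p <- numeric(0)
    batch <- 0
    while (length(kept) < n_v && batch < max_batches) {
      batch <- batch + 1
      for (j in seq_len(4 * n_v)) {
        mu <- sample(10:30, 1)
        sigma <- sample(seq(1, 3, by = 0.01), 1)
        x <- stats::rnorm(2 * n, mu, sigma)
        p <- stats::t.test(x[1:n], x[(n + 1):(2 * n)])$p.value
        if (p >= p_min) {
          kept[[length(kept) + 1]] <- x
          kept_p <- c(kept_p, p)
        }
        if (length(kept) >= 4 * n_v) break
      }
    }
    if (length(kept) < n_v) {
      stop("could not assemble enough variables passing the p-value filter")
    }
    pick <- sample.int(length(kept), n_v)
    list(vals = do.call(cbind, kept[pick]), p = kept_p[pick])
  })
  vals <- res$vals
  colnames(vals) <- paste0("X", seq_len(n_v))
  out <- tabular_dataset(vals, rep(c(1, 2), each = n_per_class))
  attr(out, "filter_pvalues") <- res$p
  out
}
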