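#' Gabriel graph of a point set
#'
#' Two points u, v are connected iff no third point lies in the closed ball
#' having the segment uv as diameter; equivalently, iff
#' `d(u,v)^2 < d(u,w)^2 + d(v,w)^2` for every other point w (the original
#' Gabriel-Sokal condition, under which a point on the ball's boundary
#' blocks the edge). Duplicate points are removed before construction.
#'
#' @param points numeric matrix, one point per row (`>= 2` distinct rows).
#' @return list with `edges` (two-column matrix of 1-based indices into the
#'   deduplicated point set, `u < v`), `lengths` (Euclidean edge lengths)
#'   and `points` (the deduplicated matrix).
#' @export
#' @examples
#' g <- gabriel_graph(rbind(c(0, 0), c(1, 0), c(2, 0)))
#' g$edges  # (1,2) and (2,3); (1,3) is blocked by the middle point
gabriel_graph <- function(points) {
  points <- as.matrix(points)
  points <- unique(points)
  p <- nrow(points)
  if (p < 2) stop("at least 2 distinct points are required")
  d2 <- as.matrix(stats::dist(points))^2
  edges <- list()
  k <- 0
  for (u in seq_len(p - 1)) {
    # blocked(v) = exists w != u,v with d2[u,w] + d2[v,w] <= d2[u,v]
    others <- seq_len(p)[-u]
    for (v in others[others > u]) {
      w <- setdiff(seq_len(p), c(u, v))
      blocked <- length(w) > 0 &&
        any(d2[u, w] + d2[v, w] <= d2[u, v] + 1e-12)
      if (!blocked) {
        k <- k + 1
        edges[[k]] <- c(u, v)
      }
    }
  }
  E <- do.call(rbind, edges)
  list(edges = E, lengths = sqrt(d2[E]), points = points)
}

#' Fit a two-component univariate Gaussian mixture to distance heights
#'
#' Model-based clustering with unequal variances, fitted by
#' expectation-maximization (via \pkg{mclust}); components are returned
#' ordered by mean. A fit is flagged degenerate when a component weight
#' falls below 0.01, the means differ by less than a tenth of the pooled
#' standard deviation, or a single-component model has the better BIC --
#' the telltales of an effectively unimodal height distribution on which
#' no meaningful cluster boundary exists.
#'
#' @param heights numeric vector of `>= 10` values with positive variance.
#' @param seed integer seed (the EM initialization used here is
#'   deterministic; the seed is kept for interface stability).
#' @return list of class `bimodal_gmm` with `pi`, `mu`, `sigma` (each
#'   length 2, ordered by mean), `loglik`, and `degenerate` flag.
#' @export
fit_bimodal_gmm <- function(heights, seed = 42) {
  heights <- as.numeric(heights)
  if (length(heights) < 10) stop("at least 10 heights are required")
  if (stats::sd(heights) == 0) stop("heights have zero variance; cannot fit a mixture")
  fit <- with_seed(seed, {
    suppressWarnings(
      mclust::Mclust(heights, G = 2, modelNames = "V", verbose = FALSE))
  })
  if (is.null(fit)) {
    # EM failed outright: report a collapsed fit
    m <- mean(heights)
    s <- stats::sd(heights)
    return(structure(list(pi = c(0.5, 0.5), mu = c(m, m), sigma = c(s, s),
                          loglik = NA_real_, degenerate = TRUE),
                     class = "bimodal_gmm"))
  }
  mu <- as.numeric(fit$parameters$mean)
  sigma <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sigma) == 1) sigma <- rep(sigma, 2)
  pi <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  mu <- mu[ord]; sigma <- sigma[ord]; pi <- pi[ord]
  fit1 <- with_seed(seed, {
    suppressWarnings(mclust::Mclust(heights, G = 1, verbose = FALSE))
  })
  unimodal <- !is.null(fit1) && is.finite(fit1$bic) && is.finite(fit$bic) &&
    fit1$bic >= fit$bic  # mclust BIC: larger is better
  pooled <- sqrt(sum(pi * sigma^2))
  degenerate <- min(pi) < 0.01 || abs(mu[2] - mu[1]) < 0.1 * pooled ||
    unimodal
  structure(list(pi = pi, mu = mu, sigma = sigma,
                 loglik = fit$loglik, degenerate = degenerate),
            class = "bimodal_gmm")
}

#' Bayes decision boundary between two Gaussian mixture components
#'
#' Returns the point x in `(mu1, mu2)` at which the two weighted component
#' densities are equal, `pi1 * N(x | mu1, sigma1) = pi2 * N(x | mu2,
#' sigma2)` -- the boundary at which posterior class membership flips.
#'
#' @param gmm a `bimodal_gmm` (or any list with `pi`, `mu`, `sigma`,
#'   components ordered by mean, `mu[1] < mu[2]`).
#' @return the boundary, a single number in `(mu[1], mu[2])`.
#' @export
#' @examples
#' bayes_boundary(list(pi = c(0.5, 0.5), mu = c(0, 10), sigma = c(1, 1)))  # 5
bayes_boundary <- function(gmm) {
  pi <- gmm$pi; mu <- gmm$mu; sigma <- gmm$sigma
  if (!(mu[1] < mu[2])) stop("component means must satisfy mu1 < mu2")
  f <- function(x) {
    log(pi[1]) + stats::dnorm(x, mu[1], sigma[1], log = TRUE) -
      log(pi[2]) - stats::dnorm(x, mu[2], sigma[2], log = TRUE)
  }
  eps <- 1e-9 * (mu[2] - mu[1])
  lo <- mu[1] + eps
  hi <- mu[2] - eps
  if (f(lo) * f(hi) > 0) {
    stop("no density crossing between the component means (pathological fit)")
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Estimate the critical generative radius from a trained grid
#'
#' The distances along Gabriel-graph edges between the prototypes of
#' occupied best-matching units (the "abstract U-matrix heights") are
#' typically bimodal: short within-cluster edges versus long between-cluster
#' edges. A two-component Gaussian mixture is fitted to these heights and
#' the Bayes decision boundary between the components is taken as the
#' critical radius r separating within- from between-cluster scales. When
#' the mixture is degenerate (effectively unimodal heights), the median
#' height is used instead and the estimate is flagged.
#'
#' @param grid a trained `esom_grid` with at least 2 occupied BMUs.
#' @param seed integer seed forwarded to the mixture fit.
#' @param multiplier scale factor applied to the boundary to obtain r
#'   (default 1: the radius is the boundary itself).
#' @return object of class `radius_estimate`: list with `au_heights`,
#'   `gmm`, `t_au` (boundary; `NA` on fallback), `r`, `degenerate`,
#'   `n_occupied`.
#' @export
critical_radius <- function(grid, seed = 42, multiplier = 1) {
  stopifnot(inherits(grid, "esom_grid"))
  if (is.null(grid$bmu)) stop("grid carries no BMU assignment; train it first")
  occ <- sort(unique(grid$bmu))
  protos <- unique(grid$weights[occ, , drop = FALSE])
  if (nrow(protos) < 2) stop("fewer than 2 distinct occupied BMU prototypes")
  gg <- gabriel_graph(protos)
  heights <- gg$lengths

  degenerate <- FALSE
  t_au <- NA_real_
  gmm <- NULL
  if (length(heights) >= 10 && stats::sd(heights) > 0) {
    gmm <- fit_bimodal_gmm(heights, seed = seed)
    if (!gmm$degenerate) {
      t_au <- tryCatch(bayes_boundary(gmm), error = function(e) NA_real_)
    }
    if (is.na(t_au)) degenerate <- TRUE
  } else {
    degenerate <- TRUE
  }
  r <- if (degenerate) stats::median(heights) else t_au
  r <- r * multiplier
  if (!is.finite(r) || r <= 0) {
    # all-equal tiny heights etc.: fall back to a strictly positive scale
    r <- max(stats::median(heights), 1e-8)
    degenerate <- TRUE
  }
  structure(list(au_heights = heights, gmm = gmm, t_au = t_au, r = r,
                 degenerate = degenerate, n_occupied = length(occ)),
            class = "radius_estimate")
}

#' @export
print.radius_estimate <- function(x, ...) {
  cat(sprintf("radius_estimate: r = %.4g (%d occupied BMUs, %d Gabriel edges)%s\n",
              x$r, x$n_occupied, length(x$au_heights),
              if (x$degenerate) " [degenerate fallback: median height]" else ""))
  if (!is.null(x$gmm) && !x$degenerate) {
    cat(sprintf("  mixture: pi = (%.2f, %.2f), mu = (%.3g, %.3g), boundary t = %.4g\n",
                x$gmm$pi[1], x$gmm$pi[2], x$gmm$mu[1], x$gmm$mu[2], x$t_au))
  }
  invisible(x)
}
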