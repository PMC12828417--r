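#' Generator configuration
#'
#' Bundles the parameters of the neighborhood sampler: the scaling constant
#' c of the sigmoid neighborhood (by default the critical radius r), the
#' number of synthetic points per original observation k, and the target
#' stratum fractions for core / intermediate / outer sampling.
#'
#' @param c neighborhood scaling constant (`> 0`), in standardized units.
#' @param k synthetic points per original observation (`>= 1`).
#' @param strata length-3 positive weights for the (core, intermediate,
#'   outer) strata; renormalized to sum to 1. Defaults `(0.85, 0.15, 0.05)`,
#'   i.e. 85% of points from the core neighborhood (p > 0.95), 15% from
#'   intermediate distances (0.10 < p < 0.95) and 5% from the outer region
#'   (p <= 0.10, d <= 2c).
#' @param seed integer seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(c, k, strata = c(0.85, 0.15, 0.05), seed = 42) {
  if (length(c) != 1 || !is.finite(c) || c <= 0) stop("c must be a single positive number")
  if (length(k) != 1 || !is.finite(k) || k < 1) stop("k must be >= 1")
  k <- as.integer(k)
  if (length(strata) != 3 || any(strata <= 0)) {
    stop("strata must be 3 positive weights")
  }
  strata <- strata / sum(strata)
  structure(list(c = c, k = k, strata = strata, seed = as.integer(seed)),
            class = "generator_config")
}

#' Engineer permuted control features
#'
#' For every original column X_j, appends a negative-control column
#' X_j_perm holding an independent random permutation of X_j's values
#' across samples. Controls retain each variable's marginal distribution
#' but carry no association with the class or the other predictors; they
#' are injected after structure learning so they cannot contaminate the
#' critical-radius estimate, yet they experience the same generative
#' augmentation as the originals -- which is exactly what makes them a
#' diagnostic for error inflation.
#'
#' @param data a [tabular_dataset] with original columns only.
#' @param seed integer seed for the permutations.
#' @return a [tabular_dataset] with `2J` columns, provenance tags and the
#'   original-to-control `counterpart_map` filled in; labels unchanged.
#' @export
engineer_controls <- function(data, seed = 42) {
  validate_dataset(data)
  if (any(data$provenance == "engineered")) {
    stop("dataset already carries engineered controls")
  }
  v <- data$values
  perm <- with_seed(seed, {
    apply(v, 2, function(col) col[sample.int(length(col))])
  })
  colnames(perm) <- paste0(colnames(v), "_perm")
  cm <- stats::setNames(colnames(perm), colnames(v))
  tabular_dataset(cbind(v, perm), data$labels,
                  provenance = c(rep("original", ncol(v)),
                                 rep("engineered", ncol(perm))),
                  counterpart_map = cm,
                  row_origin = data$row_origin)
}

#' Sigmoid neighborhood probability
#'
#' Probability that a point at distance d belongs to the neighborhood of a
#' reference point, under the sigmoid law
#' `p = 1 - 1 / (1 + exp(-10 * (d / c - 1)))`.
#' The probability is 0.5 exactly at `d = c`, close to 1 well inside the
#' neighborhood and decays rapidly beyond it.
#'
#' @param d non-negative distance(s).
#' @param c scaling constant (`> 0`) setting the effective neighborhood size.
#' @return probabilities in `(0, 1)`, strictly decreasing in `d`.
#' @export
#' @examples
#' neighborhood_probability(1, 1)   # 0.5
#' neighborhood_probability(0, 1)   # ~0.99995
neighborhood_probability <- function(d, c) {
  if (length(c) != 1 || !is.finite(c) || c <= 0) stop("c must be a single positive number")
  if (any(d < 0)) stop("distances must be non-negative")
  1 - 1 / (1 + exp(-10 * (d / c - 1)))
}

# inverse of the sigmoid neighborhood law: distance at which the
# neighborhood probability equals p (p in (0,1))
neighborhood_distance <- function(p, c) {
  c * (1 - log(p / (1 - p)) / 10)
}

# uniform direction on the unit hypersphere in J dimensions
runif_sphere <- function(n, J) {
  u <- matrix(stats::rnorm(n * J), n, J)
  u / sqrt(rowSums(u^2))
}

#' Generate synthetic points in the neighborhoods of the original points
#'
#' Draws `k` synthetic observations per original row. Each synthetic point
#' (1) is assigned a stratum (core / intermediate / outer) with the
#' configured probabilities, (2) receives a target neighborhood probability
#' drawn uniformly within its stratum's band -- core `p > 0.95`,
#' intermediate `0.10 < p < 0.95`, outer `p(2c) <= p <= 0.10` so that the
#' distance never exceeds `2c` -- (3) the sigmoid law is inverted to the
#' corresponding distance, and (4) the point is placed at that distance
#' from its seed row in a uniformly random direction of the standardized
#' feature space. Explicitly controlling the radial law this way both
#' matches the stratum fractions in expectation and avoids the
#' concentration of naive high-dimensional sampling on the hypersphere
#' surface. Every synthetic row inherits the class label of its seed row.
#'
#' Original and engineered columns (when present) are displaced jointly by
#' the same draw, so control features undergo identical augmentation
#' dynamics. Sampling happens in z-standardized space; outputs are
#' back-transformed to the original scale.
#'
#' @param data a [tabular_dataset] (any mix of original and engineered
#'   columns).
#' @param config a [generator_config]; `config$c` is interpreted in
#'   standardized units.
#' @return a [tabular_dataset] of exactly `n * k` synthetic rows
#'   (`row_origin = "generated"`), with attribute `"diagnostics"`: a data
#'   frame with per-point `seed_row`, `stratum`, `target_p` and `distance`
#'   (standardized units).
#' @export
generate_points <- function(data, config) {
  validate_dataset(data)
  stopifnot(inherits(config, "generator_config"))
  v <- data$values
  n <- nrow(v); J <- ncol(v)
  k <- config$k; cc <- config$c
  std <- standardize_values(v)
  Z <- std$z

  p_max <- neighborhood_probability(0, cc)      # p at d = 0 (just under 1)
  p_outer_min <- neighborhood_probability(2 * cc, cc)  # p at d = 2c
  bands <- rbind(core = c(0.95, p_max),
                 intermediate = c(0.10, 0.95),
                 outer = c(p_outer_min, 0.10))

  total <- n * k
  out <- with_seed(config$seed, {
    seed_row <- rep(seq_len(n), each = k)
    stratum <- sample.int(3, total, replace = TRUE, prob = config$strata)
    p_star <- stats::runif(total, bands[stratum, 1], bands[stratum, 2])
    d_star <- neighborhood_distance(p_star, cc)
    dirs <- runif_sphere(total, J)
    Znew <- Z[seed_row, , drop = FALSE] + dirs * d_star
    list(seed_row = seed_row, stratum = stratum,
         p_star = p_star, d_star = d_star, Znew = Znew)
  })

  vnew <- unstandardize_values(out$Znew, std$center, std$scale)
  colnames(vnew) <- colnames(v)
  res <- tabular_dataset(vnew, data$labels[out$seed_row],
                         provenance = data$provenance,
                         counterpart_map = data$counterpart_map,
                         row_origin = rep("generated", total))
  attr(res, "diagnostics") <- data.frame(
    seed_row = out$seed_row,
    stratum = c("core", "intermediate", "outer")[out$stratum],
    target_p = out$p_star,
    distance = out$d_star)
  res
}

#' Augment a dataset with synthetic neighborhood samples
#'
#' Appends `k` generated rows per original row (see [generate_points()]) to
#' the input, preserving class proportions exactly through label
#' inheritance. Row provenance is retained, so [drop_generated()] restores
#' the input.
#'
#' @inheritParams generate_points
#' @return a [tabular_dataset] with `n * (1 + k)` rows: originals first,
#'   then the generated block; the generation diagnostics are carried in
#'   attribute `"diagnostics"`.
#' @export
augment_dataset <- function(data, config) {
  synth <- generate_points(data, config)
  res <- tabular_dataset(rbind(data$values, synth$values),
                         factor(c(as.character(data$labels),
                                  as.character(synth$labels)),
                                levels = levels(data$labels)),
                         provenance = data$provenance,
                         counterpart_map = data$counterpart_map,
                         row_origin = c(data$row_origin, synth$row_origin))
  attr(res, "diagnostics") <- attr(synth, "diagnostics")
  res
}
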