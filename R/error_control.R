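#' Bootstrap overfitting threshold on selection-count differences
#'
#' Given the per-variable confirmed-selection counts of the permuted
#' controls (`a`) and of the original variables (`b`), draws paired
#' bootstrap resamples with replacement from each and computes the
#' difference `delta_i = b_i - a_i` for every resample. The threshold
#' `L_delta` is the empirical `q`-quantile (default the 95th percentile)
#' of this difference distribution: the largest original-minus-control
#' count difference still compatible with the baseline, unaugmented data.
#' Importance differences beyond it signal error inflation.
#'
#' @param a selection counts of the permuted (control) variables.
#' @param b selection counts of the original variables.
#' @param n_bootstrap number of bootstrap resamples (default 100000).
#' @param q quantile level in `(0, 1)` (default 0.95).
#' @param seed integer seed.
#' @return object of class `error_threshold`: list with `l_delta`, summary
#'   statistics of the difference sample (`delta_summary`), the inputs and
#'   the settings.
#' @export
#' @examples
#' bootstrap_threshold(a = c(0, 0, 1), b = c(0, 2, 3),
#'                     n_bootstrap = 1e4, seed = 1)$l_delta
bootstrap_threshold <- function(a, b, n_bootstrap = 1e5, q = 0.95, seed = 42) {
  if (length(a) == 0 || length(b) == 0) stop("a and b must be non-empty")
  if (length(q) != 1 || q <= 0 || q >= 1) stop("q must be in (0, 1)")
  n_bootstrap <- as.integer(n_bootstrap)
  delta <- with_seed(seed, {
    a_s <- a[sample.int(length(a), n_bootstrap, replace = TRUE)]
    b_s <- b[sample.int(length(b), n_bootstrap, replace = TRUE)]
    b_s - a_s
  })
  # inverse-ECDF quantile (type 1): counts are discrete, no interpolation
  l_delta <- unname(stats::quantile(delta, probs = q, type = 1))
  structure(list(l_delta = l_delta,
                 delta_summary = summary(delta),
                 a = a, b = b,
                 n_bootstrap = n_bootstrap, q = q, seed = seed),
            class = "error_threshold")
}

#' @export
print.error_threshold <- function(x, ...) {
  cat(sprintf("error_threshold: L_delta = %g (q = %.2f quantile of %d bootstrap differences)\n",
              x$l_delta, x$q, x$n_bootstrap))
  invisible(x)
}

#' Search for the largest safe augmentation level
#'
#' Starting from a control-carrying dataset, candidate augmentation levels
#' 1, 2, ... are tried in turn: the dataset is augmented at that level
#' (fresh each time, not cumulatively), selection frequencies are
#' recomputed, and the per-variable importance differences
#' `delta_I_j = count(X_j) - count(X_j_perm)` are compared against the
#' fixed baseline threshold `L_delta`. The search stops at the first level
#' at which any variable exceeds the threshold; the recommendation is that
#' level minus one -- the largest level that did NOT surpass the threshold.
#' A recommendation of 0 means "do not augment". If no level up to
#' `max_level` exceeds the threshold, `max_level` is returned with the
#' `capped` flag set.
#'
#' @param data a [tabular_dataset] that already carries engineered controls
#'   (see [engineer_controls()]).
#' @param r critical radius used as the generator scale c (`> 0`).
#' @param threshold an `error_threshold` from [bootstrap_threshold()].
#' @param runs repeated selection runs per level.
#' @param max_level largest candidate level (default 10).
#' @param seed master seed; generation and selection seeds per level are
#'   derived from it.
#' @param max_iter,alpha,num_trees forwarded to the selection runs.
#' @return object of class `stopping_result`: list with `n_gen_per_data`,
#'   `trace` (data frame: level, max delta, exceeded), `threshold`,
#'   `capped`.
#' @export
find_stopping <- function(data, r, threshold, runs = 100, max_level = 10,
                          seed = 42, max_iter = 100, alpha = 0.01,
                          num_trees = 500) {
  validate_dataset(data, require_classes = 2)
  if (!any(data$provenance == "engineered")) {
    stop("dataset must carry engineered controls; call engineer_controls() first")
  }
  if (r <= 0) stop("r must be positive")
  if (max_level < 1) stop("max_level must be >= 1")
  stopifnot(inherits(threshold, "error_threshold"))

  level_seeds <- derive_seeds(seed, 2L * max_level)
  trace <- vector("list", max_level)
  n_gen <- max_level
  capped <- TRUE
  for (level in seq_len(max_level)) {
    cfg <- generator_config(c = r, k = level, seed = level_seeds[2 * level - 1])
    aug <- augment_dataset(data, cfg)
    prof <- selection_frequencies(aug, runs = runs,
                                  seed = level_seeds[2 * level],
                                  max_iter = max_iter, alpha = alpha,
                                  num_trees = num_trees)
    di <- delta_importance(prof, data$counterpart_map)
    exceeded <- any(di > threshold$l_delta)
    trace[[level]] <- data.frame(level = level,
                                 max_delta = max(di),
                                 exceeded = exceeded)
    if (exceeded) {
      n_gen <- level - 1L
      capped <- FALSE
      break
    }
  }
  structure(list(n_gen_per_data = as.integer(n_gen),
                 trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]),
                 threshold = threshold, capped = capped),
            class = "stopping_result")
}

#' @export
print.stopping_result <- function(x, ...) {
  rec <- if (x$n_gen_per_data == 0) "0 (do not augment)" else
    sprintf("%d synthetic point(s) per original%s", x$n_gen_per_data,
            if (x$capped) " [capped at max_level]" else "")
  cat("stopping_result: recommended n_gen_per_data =", rec, "\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Default configuration for the safe-augmentation pipeline
#'
#' @param rows,cols,epochs ESOM lattice and training length.
#' @param runs repeated selection runs R per regime (default 100).
#' @param n_bootstrap bootstrap resamples for the threshold (default 100000).
#' @param q threshold quantile (default 0.95).
#' @param max_level largest augmentation level searched (default 10).
#' @param max_iter,alpha,num_trees feature-selection settings.
#' @param radius_multiplier scale applied to the Bayes boundary to obtain
#'   the generative radius (default 1).
#' @param strata core / intermediate / outer target fractions.
#' @param seed master seed for the whole run.
#' @return list of class `guard_config`.
#' @export
guard_config <- function(rows = 50, cols = 80, epochs = 24,
                         runs = 100, n_bootstrap = 1e5, q = 0.95,
                         max_level = 10, max_iter = 100, alpha = 0.01,
                         num_trees = 500, radius_multiplier = 1,
                         strata = c(0.85, 0.15, 0.05), seed = 42) {
  structure(list(rows = rows, cols = cols, epochs = epochs, runs = runs,
                 n_bootstrap = n_bootstrap, q = q, max_level = max_level,
                 max_iter = max_iter, alpha = alpha, num_trees = num_trees,
                 radius_multiplier = radius_multiplier, strata = strata,
                 seed = as.integer(seed)),
            class = "guard_config")
}

#' Safe generative augmentation with error-inflation control
#'
#' The end-to-end pipeline: (1) an ESOM is trained on the raw dataset and
#' the critical radius r estimated from its structure; (2) permuted control
#' features are engineered into a working copy; (3) repeated feature
#' selection on the unaugmented working copy yields the per-variable
#' confirmed counts of controls (`a`) and originals (`b`), from which the
#' bootstrap threshold `L_delta` is computed; (4) the stopping search finds
#' the largest augmentation level whose importance differences stay below
#' `L_delta`; (5) the original dataset -- without the engineered columns --
#' is augmented at that level. When the recommendation is 0, the input is
#' returned unchanged with a do-not-augment flag.
#'
#' @param data a [tabular_dataset] with original columns only and `>= 2`
#'   classes.
#' @param config a [guard_config].
#' @return list with `data` (the augmented -- or unchanged -- dataset, free
#'   of engineered columns) and `report`, a `run_report` collecting the
#'   radius estimate, the threshold, the stopping trace, the
#'   recommendation, per-stage seeds and any degeneracy warnings.
#' @export
safe_augment <- function(data, config = guard_config()) {
  validate_dataset(data, require_classes = 2)
  stopifnot(inherits(config, "guard_config"))
  seeds <- derive_seeds(config$seed, 6)
  warnings <- character(0)

  grid <- train_esom(data, rows = config$rows, cols = config$cols,
                     epochs = config$epochs, seed = seeds[1])
  est <- critical_radius(grid, seed = seeds[2],
                         multiplier = config$radius_multiplier)
  if (est$degenerate) {
    warnings <- c(warnings,
                  "radius estimate degenerate: median Gabriel-edge height used")
  }

  d_temp <- engineer_controls(data, seed = seeds[3])
  baseline <- selection_frequencies(d_temp, runs = config$runs,
                                    seed = seeds[4],
                                    max_iter = config$max_iter,
                                    alpha = config$alpha,
                                    num_trees = config$num_trees)
  tab <- baseline$table
  a <- tab$selection_count[tab$provenance == "engineered"]
  b <- tab$selection_count[tab$provenance == "original"]
  thr <- bootstrap_threshold(a, b, n_bootstrap = config$n_bootstrap,
                             q = config$q, seed = seeds[5])

  stopres <- find_stopping(d_temp, r = est$r, threshold = thr,
                           runs = config$runs, max_level = config$max_level,
                           seed = seeds[6], max_iter = config$max_iter,
                           alpha = config$alpha,
                           num_trees = config$num_trees)

  g <- stopres$n_gen_per_data
  if (g >= 1) {
    cfg <- generator_config(c = est$r, k = g, strata = config$strata,
                            seed = seeds[6])
    out <- augment_dataset(data, cfg)
  } else {
    out <- data
  }

  report <- structure(
    list(config = unclass(config),
         seeds = stats::setNames(as.list(seeds),
                                 c("esom", "radius", "controls",
                                   "baseline_selection", "bootstrap",
                                   "stopping")),
         radius = list(r = est$r, t_au = est$t_au,
                       degenerate = est$degenerate,
                       n_occupied = est$n_occupied,
                       n_edges = length(est$au_heights)),
         threshold = list(l_delta = thr$l_delta, q = thr$q,
                          n_bootstrap = thr$n_bootstrap,
                          a_summary = as.list(summary(a)),
                          b_summary = as.list(summary(b))),
         baseline_counts = stats::setNames(as.list(tab$selection_count),
                                           tab$feature),
         stopping = list(n_gen_per_data = g, capped = stopres$capped,
                         trace = stopres$trace),
         recommendation = if (g == 0) "do not augment" else
           sprintf("augment with %d synthetic point(s) per original", g),
         do_not_augment = (g == 0),
         warnings = warnings),
    class = "run_report")
  list(data = out, report = report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  critical radius r = %.4g%s\n", x$radius$r,
              if (x$radius$degenerate) " (degenerate fallback)" else ""))
  cat(sprintf("  threshold L_delta = %g (q = %.2f, %d resamples)\n",
              x$threshold$l_delta, x$threshold$q, x$threshold$n_bootstrap))
  cat(sprintf("  recommendation: %s%s\n", x$recommendation,
              if (isTRUE(x$stopping$capped)) " (search capped at max_level)" else ""))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
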