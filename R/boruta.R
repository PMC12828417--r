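#' All-relevant feature selection against shadow features
#'
#' A Boruta-style wrapper around a random-forest classifier. In each
#' iteration every still-active feature is duplicated into a freshly
#' permuted "shadow" copy, a forest is trained on the joined table, and
#' features are scored by out-of-bag permutation importance (the decrease
#' in OOB prediction accuracy when the feature's values are permuted,
#' scaled by its standard error -- the Z-score used by the reference
#' algorithm). A
#' feature scores a "hit" when its importance exceeds the maximum shadow
#' importance of that iteration. Across iterations, two-sided binomial
#' tests on the hit counts (Bonferroni-adjusted over the active features)
#' classify features as `confirmed` (significantly more hits than chance),
#' `rejected` (significantly fewer; dropped from subsequent iterations) or
#' `tentative`. Shadows are internal and never appear among the decisions.
#'
#' @param data a [tabular_dataset] with `>= 2` classes.
#' @param max_iter maximum number of iterations (default 100).
#' @param alpha significance level of the binomial decision tests
#'   (default 0.01).
#' @param seed integer seed.
#' @param num_trees trees per forest (default 500).
#' @return list with `decision` (named factor over all non-shadow features:
#'   confirmed / tentative / rejected), `importance` (named numeric, mean
#'   permutation importance over the iterations in which the feature was
#'   active), `hits`, `iterations`, `shadow_max` (per-iteration maximum
#'   shadow importance).
#' @export
boruta_select <- function(data, max_iter = 100, alpha = 0.01, seed = 42,
                          num_trees = 500) {
  validate_dataset(data, require_classes = 2)
  if (max_iter < 1) stop("max_iter must be >= 1")
  v <- data$values
  feats <- colnames(v)
  J <- length(feats)
  y <- droplevels(data$labels)

  hits <- stats::setNames(integer(J), feats)
  active_iters <- stats::setNames(integer(J), feats)
  imp_sum <- stats::setNames(numeric(J), feats)
  decision <- stats::setNames(rep("tentative", J), feats)
  shadow_max <- numeric(0)

  iter_seeds <- derive_seeds(seed, 2L * max_iter)
  it <- 0
  while (it < max_iter && any(decision == "tentative")) {
    it <- it + 1
    active <- names(decision)[decision != "rejected"]
    A <- v[, active, drop = FALSE]
    shadows <- with_seed(iter_seeds[2 * it - 1], {
      sh <- apply(A, 2, function(col) col[sample.int(length(col))])
      sh <- matrix(sh, nrow = nrow(A),
                   dimnames = list(NULL, paste0(".shadow.", active)))
      # keep at least 5 shadow features so the max-shadow reference is
      # stable even when few candidates remain
      while (ncol(sh) < 5) {
        src <- active[sample.int(length(active), 1)]
        extra <- A[sample.int(nrow(A)), src]
        sh <- cbind(sh, extra)
        colnames(sh)[ncol(sh)] <- paste0(".shadow.dup", ncol(sh))
      }
      sh
    })
    df <- data.frame(A, shadows, check.names = FALSE)
    df$.class. <- y
    fit <- ranger::ranger(
      dependent.variable.name = ".class.", data = df,
      num.trees = num_trees,
      mtry = max(1, floor(sqrt(ncol(df) - 1))),
      importance = "permutation",
      scale.permutation.importance = TRUE,
      seed = iter_seeds[2 * it],
      num.threads = 1, verbose = FALSE)
    imp <- fit$variable.importance
    imp[!is.finite(imp)] <- 0  # degenerate trees can yield NaN importances
    smax <- max(imp[startsWith(names(imp), ".shadow.")])
    shadow_max <- c(shadow_max, smax)
    fi <- imp[active]
    hits[active] <- hits[active] + as.integer(fi > smax)
    active_iters[active] <- active_iters[active] + 1L
    imp_sum[active] <- imp_sum[active] + fi

    # two-sided binomial decisions, Bonferroni-adjusted over all features
    und <- names(decision)[decision == "tentative"]
    m_adj <- J
    for (f in und) {
      t_f <- active_iters[f]
      p_hi <- stats::pbinom(hits[f] - 1, t_f, 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[f], t_f, 0.5)
      if (min(1, p_hi * m_adj) < alpha) decision[f] <- "confirmed"
      else if (min(1, p_lo * m_adj) < alpha) decision[f] <- "rejected"
    }
  }
  list(decision = factor(decision, levels = c("confirmed", "tentative", "rejected")),
       importance = ifelse(active_iters > 0, imp_sum / pmax(active_iters, 1L), NA_real_),
       hits = hits, iterations = it, shadow_max = shadow_max)
}

#' Selection frequencies over repeated feature-selection runs
#'
#' Repeats [boruta_select()] with per-run seeds derived from one master
#' seed and aggregates, per feature, the number of runs in which it was
#' confirmed important, together with its mean importance score. These
#' selection counts are the importance currency of the error-inflation
#' control: the difference between a variable's count and its engineered
#' counterpart's count is what gets compared against the bootstrap
#' threshold.
#'
#' @param data a [tabular_dataset].
#' @param runs number of repeated runs R (default 100).
#' @param seed master seed; per-run seeds are derived from it.
#' @param max_iter,alpha,num_trees forwarded to [boruta_select()].
#' @return object of class `selection_profile`: data frame `table` with
#'   columns feature / provenance / importance / selection_count plus
#'   fields `runs`, `shadow_max_trace` and the per-run decisions.
#' @export
selection_frequencies <- function(data, runs = 100, seed = 42,
                                  max_iter = 100, alpha = 0.01,
                                  num_trees = 500) {
  if (runs < 1) stop("runs must be >= 1")
  run_seeds <- derive_seeds(seed, runs)
  feats <- colnames(data$values)
  counts <- stats::setNames(integer(length(feats)), feats)
  imp_mat <- matrix(NA_real_, nrow = runs, ncol = length(feats),
                    dimnames = list(NULL, feats))
  shadow_trace <- vector("list", runs)
  for (rix in seq_len(runs)) {
    res <- boruta_select(data, max_iter = max_iter, alpha = alpha,
                         seed = run_seeds[rix], num_trees = num_trees)
    counts <- counts + as.integer(res$decision == "confirmed")
    imp_mat[rix, ] <- res$importance[feats]
    shadow_trace[[rix]] <- res$shadow_max
  }
  tab <- data.frame(
    feature = feats,
    provenance = data$provenance,
    importance = colMeans(imp_mat, na.rm = TRUE),
    selection_count = as.integer(counts),
    row.names = NULL)
  structure(list(table = tab, runs = runs,
                 shadow_max_trace = shadow_trace,
                 counterpart_map = data$counterpart_map),
            class = "selection_profile")
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf("selection_profile: %d features over %d runs\n",
              nrow(x$table), x$runs))
  print(utils::head(x$table[order(-x$table$selection_count), ], 10),
        row.names = FALSE)
  invisible(x)
}

#' Importance difference between original variables and their controls
#'
#' For every original variable X_j with an engineered counterpart, computes
#' `delta_I_j = I(X_j) - I(X_j_perm)` on the selection-count scale: the
#' number of runs in which the original was confirmed minus the number in
#' which its permuted control was. Consistently positive values indicate
#' genuine predictive signal; values near zero (or negative) indicate
#' spurious importance.
#'
#' @param profile a `selection_profile`.
#' @param counterpart_map named character vector (original -> engineered
#'   column name); defaults to the map stored in the profile.
#' @return named numeric vector of differences, one per original variable.
#' @export
delta_importance <- function(profile, counterpart_map = profile$counterpart_map) {
  tab <- profile$table
  counts <- stats::setNames(tab$selection_count, tab$feature)
  orig <- names(counterpart_map)
  eng <- unname(counterpart_map)
  if (length(orig) == 0) stop("no engineered counterparts available")
  missing <- c(setdiff(orig, names(counts)), setdiff(eng, names(counts)))
  if (length(missing) > 0) {
    stop("counterpart columns missing from profile: ",
         paste(missing, collapse = ", "))
  }
  stats::setNames(as.numeric(counts[orig]) - as.numeric(counts[eng]), orig)
}
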