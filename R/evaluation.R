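#' Per-variable significance of class differences
#'
#' Two classes: a Welch two-sample t-test per variable; more than two
#' classes: a one-way ANOVA F-test per variable. No multiplicity
#' correction is applied -- these raw p-values feed a rank correlation,
#' not a decision rule. Variables with zero variance in every class are
#' assigned p = 1 and flagged.
#'
#' @param data a [tabular_dataset] with `>= 2` classes.
#' @param var_equal assume equal variances in the two-class t-test
#'   (default `FALSE`: Welch).
#' @return named numeric vector of p-values (one per column), with
#'   attribute `"degenerate"` naming zero-variance columns, and
#'   `"test"` (`"t"` or `"anova"`).
#' @export
per_variable_pvalues <- function(data, var_equal = FALSE) {
  validate_dataset(data, require_classes = 2)
  y <- droplevels(data$labels)
  two <- nlevels(y) == 2
  v <- data$values
  degen <- character(0)
  p <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    if (all(tapply(x, y, stats::var) %in% c(0, NA))) {
      degen <<- c(degen, colnames(v)[j])
      return(1)
    }
    if (two) {
      g <- split(x, y)
      stats::t.test(g[[1]], g[[2]], var.equal = var_equal)$p.value
    } else {
      stats::oneway.test(x ~ y, var.equal = TRUE)$p.value
    }
  }, numeric(1))
  names(p) <- colnames(v)
  attr(p, "degenerate") <- degen
  attr(p, "test") <- if (two) "t" else "anova"
  p
}

#' Agreement between statistical significance and corrected selection
#' frequency
#'
#' For every original variable, the selection frequency corrected for its
#' engineered counterpart, `count(X_j) - count(X_j_perm)`, is correlated
#' with the variable's p-value using Kendall's tau (tau-b, tie-corrected --
#' selection counts tie heavily). A strongly negative tau means variables
#' with smaller p-values are selected more often: the feature-selection
#' ranking agrees with the significance ranking. Tau is reported as `NA`
#' when either vector is constant, in which case the correlation cannot be
#' computed.
#'
#' @param pvalues named p-value vector from [per_variable_pvalues()]
#'   (original variables; extra entries are ignored).
#' @param profile a `selection_profile` covering the original variables
#'   and their engineered counterparts.
#' @param counterpart_map named character vector (original -> engineered);
#'   defaults to the profile's stored map.
#' @param regime free-text label for the data regime (e.g. `"original"`,
#'   `"augmented_1"`), carried into the result.
#' @return object of class `agreement_result`: list with `tau`, `tau_p`,
#'   `table` (variable, p_value, corrected_frequency), `regime`.
#' @export
significance_selection_agreement <- function(pvalues, profile,
                                             counterpart_map = profile$counterpart_map,
                                             regime = "original") {
  di <- delta_importance(profile, counterpart_map)
  vars <- names(di)
  if (!all(vars %in% names(pvalues))) {
    stop("p-values missing for variables: ",
         paste(setdiff(vars, names(pvalues)), collapse = ", "))
  }
  pv <- as.numeric(pvalues[vars])
  if (stats::sd(pv) == 0 || stats::sd(di) == 0) {
    tau <- NA_real_
    tau_p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(pv, di, method = "kendall"))
    tau <- unname(ct$estimate)
    tau_p <- ct$p.value
  }
  structure(list(tau = tau, tau_p = tau_p,
                 table = data.frame(variable = vars, p_value = pv,
                                    corrected_frequency = as.numeric(di)),
                 regime = regime),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  if (is.na(x$tau)) {
    cat(sprintf("agreement_result [%s]: tau = NA (constant input, correlation not computable)\n",
                x$regime))
  } else {
    cat(sprintf("agreement_result [%s]: Kendall tau = %.3f (p = %.3g) over %d variables\n",
                x$regime, x$tau, x$tau_p, nrow(x$table)))
  }
  invisible(x)
}
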