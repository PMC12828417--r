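#' Construct a tabular dataset with class labels and column provenance
#'
#' The central container of the package: an `n x J` numeric feature matrix
#' together with a categorical class vector and per-column provenance tags
#' distinguishing original measurements from engineered (permuted) control
#' features. All downstream stages -- structure learning, augmentation,
#' feature selection and evaluation -- operate on this class.
#'
#' @param values numeric matrix or data frame of features (rows =
#'   observations, columns = variables). Coerced to a numeric matrix.
#' @param labels vector of class labels, one per row. Coerced to factor.
#' @param feature_names optional character vector of column names; defaults
#'   to the column names of `values` or `X1..XJ`.
#' @param provenance per-column tag, either `"original"` or `"engineered"`.
#'   Defaults to all-original.
#' @param counterpart_map named character vector mapping original column
#'   names to the names of their engineered counterparts (empty when no
#'   controls are present).
#' @param row_origin per-row tag, `"original"` or `"generated"`.
#'
#' @return An object of class `tabular_dataset`: a list with elements
#'   `values`, `labels`, `provenance`, `counterpart_map`, `row_origin`.
#' @export
#' @examples
#' d <- tabular_dataset(matrix(rnorm(40), 10, 4), rep(c("a", "b"), 5))
#' dim(d)
tabular_dataset <- function(values, labels, feature_names = NULL,
                            provenance = NULL, counterpart_map = character(),
                            row_origin = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(feature_names)) {
    colnames(values) <- feature_names
  } else if (is.null(colnames(values))) {
    colnames(values) <- paste0("X", seq_len(ncol(values)))
  }
  labels <- factor(labels)
  if (is.null(provenance)) provenance <- rep("original", ncol(values))
  if (is.null(row_origin)) row_origin <- rep("original", nrow(values))
  obj <- structure(
    list(values = values, labels = labels,
         provenance = provenance, counterpart_map = counterpart_map,
         row_origin = row_origin),
    class = "tabular_dataset")
  validate_dataset(obj)
  obj
}

#' Validate a tabular dataset
#'
#' Checks the container invariants: no missing or non-finite feature values,
#' at least two rows and one column, label length matching the row count,
#' and a consistent counterpart map in which every engineered column is
#' paired with exactly one original column.
#'
#' @param data a [tabular_dataset].
#' @param require_classes minimum number of distinct classes required
#'   (use 2 for stages that model the class structure).
#' @return `data`, invisibly. Errors on violation.
#' @export
validate_dataset <- function(data, require_classes = 1) {
  stopifnot(inherits(data, "tabular_dataset"))
  v <- data$values
  if (!is.numeric(v)) stop("feature values must be numeric")
  if (anyNA(v) || !all(is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-finite feature value at row %d, column '%s'",
                 bad[1], colnames(v)[bad[2]]))
  }
  if (nrow(v) < 2) stop("at least 2 observations are required")
  if (ncol(v) < 1) stop("at least 1 feature is required")
  if (length(data$labels) != nrow(v)) stop("labels must have one entry per row")
  if (length(data$provenance) != ncol(v)) {
    stop("provenance must have one entry per column")
  }
  if (!all(data$provenance %in% c("original", "engineered"))) {
    stop("provenance tags must be 'original' or 'engineered'")
  }
  if (!all(data$row_origin %in% c("original", "generated"))) {
    stop("row_origin tags must be 'original' or 'generated'")
  }
  eng <- colnames(v)[data$provenance == "engineered"]
  cm <- data$counterpart_map
  if (length(eng) > 0 || length(cm) > 0) {
    if (anyDuplicated(unname(cm)) > 0) {
      stop("an engineered column is mapped to more than one original column")
    }
    if (!setequal(unname(cm), eng)) {
      stop("counterpart_map must pair every engineered column with exactly one original column")
    }
    if (!all(names(cm) %in% colnames(v)[data$provenance == "original"])) {
      stop("counterpart_map keys must be original column names")
    }
  }
  if (nlevels(droplevels(data$labels)) < require_classes) {
    stop(sprintf("at least %d distinct classes are required", require_classes))
  }
  invisible(data)
}

#' @export
dim.tabular_dataset <- function(x) dim(x$values)

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("tabular_dataset: %d observations x %d features (%d original, %d engineered)\n",
              nrow(x$values), ncol(x$values),
              sum(x$provenance == "original"), sum(x$provenance == "engineered")))
  cat("classes:", paste(sprintf("%s (%d)", levels(x$labels), table(x$labels)),
                        collapse = ", "), "\n")
  gen <- sum(x$row_origin == "generated")
  if (gen > 0) cat(sprintf("rows: %d original + %d generated\n",
                           sum(x$row_origin == "original"), gen))
  invisible(x)
}

#' Keep only the original-measurement columns of a dataset
#'
#' Drops engineered control columns (and the counterpart map); used before
#' the final generation step, which operates on the original variables only.
#'
#' @param data a [tabular_dataset].
#' @return a [tabular_dataset] containing only columns tagged `"original"`.
#' @export
drop_engineered <- function(data) {
  keep <- data$provenance == "original"
  tabular_dataset(data$values[, keep, drop = FALSE], data$labels,
                  provenance = rep("original", sum(keep)),
                  row_origin = data$row_origin)
}

#' Keep only the original (non-generated) rows of a dataset
#'
#' Inverse of augmentation: removes all synthetic rows, restoring the seed
#' dataset exactly.
#'
#' @param data a [tabular_dataset].
#' @return a [tabular_dataset] containing only rows tagged `"original"`.
#' @export
drop_generated <- function(data) {
  keep <- data$row_origin == "original"
  tabular_dataset(data$values[keep, , drop = FALSE],
                  data$labels[keep],
                  provenance = data$provenance,
                  counterpart_map = data$counterpart_map,
                  row_origin = rep("original", sum(keep)))
}

# z-standardization used by all distance-based stages. Constant columns get
# scale 1 so they map to 0 rather than NaN.
standardize_values <- function(values, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(values)
  if (is.null(scale)) {
    scale <- apply(values, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  z <- sweep(sweep(values, 2, center, "-"), 2, scale, "/")
  list(z = z, center = center, scale = scale)
}

unstandardize_values <- function(z, center, scale) {
  sweep(sweep(z, 2, scale, "*"), 2, center, "+")
}
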