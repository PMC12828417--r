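#' Read a delimited dataset into a tabular dataset
#'
#' Reads a delimited text file with a header row, takes one column as the
#' class target and coerces all remaining columns to numeric features.
#' Rows containing missing values are rejected with their coordinates.
#'
#' @param path file path.
#' @param target_column name of the class column.
#' @param delimiter field delimiter (default `","`).
#' @return a [tabular_dataset] with provenance initialized to
#'   `"original"`. A column named `__origin` (as written by
#'   [write_outputs()]) is used for row provenance if present.
#' @export
read_dataset <- function(path, target_column, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!target_column %in% names(df)) {
    stop(sprintf("target column '%s' not found in %s", target_column, path))
  }
  labels <- df[[target_column]]
  df[[target_column]] <- NULL
  row_origin <- NULL
  if ("__origin" %in% names(df)) {
    row_origin <- df[["__origin"]]
    df[["__origin"]] <- NULL
  }
  for (nm in names(df)) {
    col <- df[[nm]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric feature value at row %d, column '%s'",
                     bad[1], nm))
      }
      df[[nm]] <- num
    }
  }
  miss <- which(is.na(as.matrix(df)), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    stop(sprintf("missing value at row %d, column '%s' (%d missing cells in total)",
                 miss[1, 1], names(df)[miss[1, 2]], nrow(miss)))
  }
  tabular_dataset(as.matrix(df), labels, row_origin = row_origin)
}

#' Write a dataset to delimited text
#'
#' Writes the feature table, the class column and the per-row `__origin`
#' provenance column with full double precision, so that re-reading
#' reproduces the values.
#'
#' @param data a [tabular_dataset].
#' @param path output file path (directories are created).
#' @param target_column name for the class column (default `"Class"`).
#' @param delimiter field delimiter.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, target_column = "Class",
                          delimiter = ",") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(data$values, check.names = FALSE)
  df[[target_column]] <- as.character(data$labels)
  df[["__origin"]] <- data$row_origin
  # full precision so that the round trip is exact to >= 12 significant digits
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write the full artifact set of a pipeline run
#'
#' Emits three files under a common prefix: the (augmented) dataset as CSV
#' with the `__origin` provenance column, the run report as JSON, and the
#' baseline selection profile as CSV.
#'
#' @param data a [tabular_dataset].
#' @param report a `run_report` from [safe_augment()].
#' @param out_prefix path prefix; `<prefix>.csv`, `<prefix>_report.json`
#'   and `<prefix>_selection.csv` are written (directories are created).
#' @param target_column name for the class column.
#' @param profile optional `selection_profile` to serialize; when `NULL`,
#'   the baseline counts stored in the report are written.
#' @return named character vector of the file paths, invisibly.
#' @export
write_outputs <- function(data, report, out_prefix, target_column = "Class",
                          profile = NULL) {
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  data_path <- paste0(out_prefix, ".csv")
  report_path <- paste0(out_prefix, "_report.json")
  sel_path <- paste0(out_prefix, "_selection.csv")
  write_dataset(data, data_path, target_column = target_column)
  write_report(report, report_path)
  if (!is.null(profile)) {
    utils::write.csv(profile$table, sel_path, row.names = FALSE)
  } else {
    counts <- report$baseline_counts
    utils::write.csv(data.frame(feature = names(counts),
                                selection_count = unlist(counts)),
                     sel_path, row.names = FALSE)
  }
  invisible(c(data = data_path, report = report_path, selection = sel_path))
}

#' Serialize a run report to JSON
#'
#' @param report a `run_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read a run report back from JSON
#'
#' @param path file written by [write_report()].
#' @return a `run_report` list.
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_report")
}

# strip S3 classes recursively so jsonlite serializes plain structures
unclass_deep <- function(x) {
  if (inherits(x, "data.frame")) {
    class(x) <- "data.frame"
    return(x)
  }
  if (is.list(x)) return(lapply(x, unclass_deep))
  if (is.object(x)) return(unclass(x))
  x
}
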