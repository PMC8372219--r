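# Dataset container: a data.frame of samples x columns with a designated
# outcome column, optional per-sample group labels, and an outcome kind
# (binary / multiclass / continuous).  Rows are identified positionally.

MISSING_TOKENS <- c("", "na", "nan", "null")

OUTCOME_KINDS <- c("binary", "multiclass", "continuous")

is_missing_token <- function(x) {
  tolower(trimws(x)) %in% MISSING_TOKENS
}

# Parse a character vector into numeric if every non-missing entry parses;
# otherwise keep it as character. Warns on genuinely mixed columns.
parse_column <- function(x, name = "column") {
  x <- as.character(x)
  x[is_missing_token(x)] <- NA_character_
  nonmiss <- x[!is.na(x)]
  if (length(nonmiss) == 0L) {
    return(as.numeric(x))
  }
  num <- suppressWarnings(as.numeric(nonmiss))
  if (!anyNA(num)) {
    out <- suppressWarnings(as.numeric(x))
    return(out)
  }
  if (any(!is.na(num))) {
    warning(sprintf(
      "column '%s' mixes numeric and non-numeric values; treating it as categorical",
      name
    ), call. = FALSE)
  }
  x
}

infer_outcome_kind <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("outcome column has no non-missing values", call. = FALSE)
  distinct <- unique(values)
  numeric_ok <- !anyNA(suppressWarnings(as.numeric(as.character(distinct))))
  if (length(distinct) < 2L) {
    stop("outcome has a single level; at least two are required", call. = FALSE)
  }
  if (length(distinct) == 2L) return("binary")
  if (numeric_ok && length(distinct) > 10L) return("continuous")
  "multiclass"
}

#' Construct a dataset for the pipeline
#'
#' Bundles a feature table with its outcome column, optional group labels and
#' the outcome kind. `read_dataset()` is the file-based counterpart.
#'
#' @param table A data.frame containing the outcome column and all feature
#'   columns.
#' @param outcome_name Name of the outcome column in `table`.
#' @param group_column Optional name of a column holding per-sample group
#'   labels (e.g. batch or site); it is removed from the feature set and kept
#'   as metadata for grouped splitting.
#' @param id_column Optional name of a sample-identifier column; removed from
#'   the feature set and kept as metadata.
#' @param outcome_kind One of `"binary"`, `"multiclass"`, `"continuous"`, or
#'   `NULL` to infer: non-numeric or few-valued outcomes are categorical
#'   (binary with exactly two levels); all-numeric outcomes with more than 10
#'   distinct values are continuous.
#' @return An object of class `ml_dataset` with elements `table` (outcome +
#'   features), `outcome_name`, `feature_names`, `group_labels` (or `NULL`),
#'   `sample_ids` (or `NULL`) and `outcome_kind`.
#' @examples
#' d <- ml_dataset(data.frame(dx = c("a", "b", "a", "b"), x = 1:4), "dx")
#' d$outcome_kind
#' @export
ml_dataset <- function(table, outcome_name, group_column = NULL,
                       id_column = NULL, outcome_kind = NULL) {
  if (!is.data.frame(table)) stop("`table` must be a data.frame", call. = FALSE)
  nm <- names(table)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate column names: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")), call. = FALSE)
  }
  if (!outcome_name %in% nm) {
    stop(sprintf("outcome column '%s' not found in the table", outcome_name),
         call. = FALSE)
  }
  if (nrow(table) < 2L) stop("at least 2 samples are required", call. = FALSE)

  sample_ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% nm) {
      stop(sprintf("id column '%s' not found", id_column), call. = FALSE)
    }
    sample_ids <- as.character(table[[id_column]])
    table[[id_column]] <- NULL
  }
  group_labels <- NULL
  if (!is.null(group_column)) {
    if (!group_column %in% names(table)) {
      stop(sprintf("group column '%s' not found", group_column), call. = FALSE)
    }
    group_labels <- as.character(table[[group_column]])
    table[[group_column]] <- NULL
  }

  outcome <- table[[outcome_name]]
  if (all(is.na(outcome)) ||
      (is.character(outcome) && all(is_missing_token(as.character(outcome)) | is.na(outcome)))) {
    stop(sprintf("outcome column '%s' is entirely missing", outcome_name), call. = FALSE)
  }
  if (is.null(outcome_kind)) {
    outcome_kind <- infer_outcome_kind(outcome)
  }
  outcome_kind <- match.arg(outcome_kind, OUTCOME_KINDS)
  if (outcome_kind == "binary" &&
      length(unique(outcome[!is.na(outcome)])) != 2L) {
    stop("outcome_kind = 'binary' requires exactly 2 distinct non-missing values",
         call. = FALSE)
  }
  if (outcome_kind == "continuous") {
    table[[outcome_name]] <- as.numeric(as.character(outcome))
  } else {
    table[[outcome_name]] <- as.character(outcome)
  }

  feature_names <- setdiff(names(table), outcome_name)
  if (length(feature_names) == 0L) stop("no feature columns found", call. = FALSE)
  structure(
    list(
      table = table,
      outcome_name = outcome_name,
      feature_names = feature_names,
      group_labels = group_labels,
      sample_ids = sample_ids,
      outcome_kind = outcome_kind
    ),
    class = "ml_dataset"
  )
}

#' Read a delimited feature table with an outcome column
#'
#' Reads a CSV/TSV file with a header row and builds an [ml_dataset].
#' Column kinds are inferred per column: a feature is continuous when every
#' non-missing entry parses as a number, and categorical otherwise. Missing
#' value tokens (`""`, `"NA"`, `"NaN"`, `"null"`, case-insensitive) are mapped
#' to `NA`. Inference is deterministic and independent of row order.
#'
#' @param path Path to the delimited file.
#' @param outcome_name Name of the outcome column.
#' @param delimiter Field delimiter; `NULL` auto-detects from the extension
#'   (`.tsv` reads tab, anything else comma).
#' @param group_column,id_column,outcome_kind Passed to [ml_dataset()].
#' @return An `ml_dataset`.
#' @export
read_dataset <- function(path, outcome_name, delimiter = NULL,
                         group_column = NULL, id_column = NULL,
                         outcome_kind = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (anyDuplicated(names(raw))) {
    stop(sprintf("duplicate column names in %s: %s", path,
                 paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", ")),
         call. = FALSE)
  }
  if (!outcome_name %in% names(raw)) {
    stop(sprintf("outcome column '%s' not found in %s", outcome_name, path),
         call. = FALSE)
  }
  parsed <- as.data.frame(
    lapply(stats::setNames(names(raw), names(raw)),
           function(nm) parse_column(raw[[nm]], nm)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(parsed) <- names(raw)
  ml_dataset(parsed, outcome_name, group_column = group_column,
             id_column = id_column, outcome_kind = outcome_kind)
}

#' Write tabular records as CSV
#'
#' Writes a data.frame as an RFC-4180-style CSV with a header row; values
#' round-trip through [read_dataset()] / `read.csv()`. An empty data.frame
#' yields a header-only file.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows, check.names = FALSE, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(rows, path, row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("cannot write to '%s': %s", path,
                                conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

# ---- accessors / helpers -------------------------------------------------

dataset_features <- function(dataset) {
  dataset$table[dataset$feature_names]
}

dataset_outcome <- function(dataset) {
  dataset$table[[dataset$outcome_name]]
}

# Positional subset preserving all metadata.
subset_dataset <- function(dataset, idx) {
  out <- dataset
  out$table <- dataset$table[idx, , drop = FALSE]
  rownames(out$table) <- NULL
  if (!is.null(dataset$group_labels)) out$group_labels <- dataset$group_labels[idx]
  if (!is.null(dataset$sample_ids)) out$sample_ids <- dataset$sample_ids[idx]
  out
}

# Feature matrix for model fitting; errors if any feature is non-numeric.
dataset_matrix <- function(dataset) {
  feats <- dataset_features(dataset)
  bad <- names(feats)[!vapply(feats, is.numeric, TRUE)]
  if (length(bad)) {
    stop(sprintf("non-numeric features present (%s); run preprocess_data() first",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  as.matrix(feats)
}

#' @export
print.ml_dataset <- function(x, ...) {
  cat(sprintf("<ml_dataset> %d samples x %d features, outcome '%s' (%s)\n",
              nrow(x$table), length(x$feature_names), x$outcome_name,
              x$outcome_kind))
  if (!is.null(x$group_labels)) {
    cat(sprintf("  groups: %d levels\n", length(unique(x$group_labels))))
  }
  kinds <- vapply(dataset_features(x), is.numeric, TRUE)
  cat(sprintf("  features: %d continuous, %d categorical\n",
              sum(kinds), sum(!kinds)))
  invisible(x)
}
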