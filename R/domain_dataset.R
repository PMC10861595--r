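#' Construct a domain dataset
#'
#' A `domain_dataset` holds one domain's samples-by-features matrix together
#' with optional integer class labels and feature names. It is the common
#' currency of every stage in the package: the labeled source cohort and the
#' unlabeled target cohort are both `domain_dataset` objects.
#'
#' Labels follow the convention `y` in `{1, ..., C}` with `C >= 2` and every
#' class populated. For binary fall-risk data the documented (arbitrary)
#' mapping is non-faller = 1, faller = 2, so the minority/positive class is 2.
#'
#' @param features numeric matrix, n_samples x n_features; all values finite.
#' @param labels optional integer vector of length `nrow(features)` with
#'   values exactly `{1..C}` for some `C >= 2`.
#' @param feature_names optional character vector, length `ncol(features)`.
#'   Defaults to the matrix column names when present.
#' @param domain_tag free-text tag, conventionally `"source"` or `"target"`.
#' @return an object of class `domain_dataset`.
#' @examples
#' d <- domain_dataset(matrix(rnorm(20), 10, 2), labels = rep(1:2, 5),
#'                     domain_tag = "source")
#' d
#' @export
domain_dataset <- function(features, labels = NULL, feature_names = NULL,
                           domain_tag = "unspecified") {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) < 1L || ncol(features) < 1L) {
    stop("features must have at least one row and one column")
  }
  if (any(!is.finite(features))) {
    bad <- which(!is.finite(features), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite feature value at row %d, column %d",
                 bad[1], bad[2]))
  }
  if (is.null(feature_names) && !is.null(colnames(features))) {
    feature_names <- colnames(features)
  }
  if (!is.null(feature_names)) {
    if (length(feature_names) != ncol(features)) {
      stop("feature_names length must match the number of feature columns")
    }
    colnames(features) <- feature_names
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(features)) {
      stop("labels length must equal the number of samples")
    }
    if (any(!is.finite(labels)) || any(labels != round(labels))) {
      stop("labels must be finite integers")
    }
    labels <- as.integer(labels)
    cls <- sort(unique(labels))
    if (!identical(cls, seq_len(max(cls))) || max(cls) < 2L) {
      stop("labels must cover {1..C} for some C >= 2, every class present")
    }
  }
  structure(
    list(features = features, labels = labels,
         feature_names = feature_names, domain_tag = as.character(domain_tag)),
    class = "domain_dataset"
  )
}

#' @export
print.domain_dataset <- function(x, ...) {
  cat(sprintf("<domain_dataset '%s'> %d samples x %d features",
              x$domain_tag, nrow(x$features), ncol(x$features)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf("; labels: %s",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  } else {
    cat("; unlabeled")
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.domain_dataset <- function(x) dim(x$features)

n_samples <- function(x) nrow(x$features)
n_features <- function(x) ncol(x$features)

# replace the feature matrix, keeping labels/tag; names follow new columns
set_features <- function(data, features, feature_names = NULL) {
  domain_dataset(features, labels = data$labels,
                 feature_names = feature_names, domain_tag = data$domain_tag)
}

#' Drop the labels of a dataset
#'
#' Returns a copy without labels — used to hold ground truth back from the
#' adaptation methods while keeping it for evaluation.
#'
#' @param data a [domain_dataset()].
#' @return the same dataset, unlabeled.
#' @export
strip_labels <- function(data) {
  d <- data
  d$labels <- NULL
  d
}

#' Read a domain dataset from a delimited text file
#'
#' Reads a comma-separated table with a mandatory header row into a
#' [domain_dataset()]. When `label_column` is given, that column is removed
#' from the feature block and parsed as integer class labels. Any missing or
#' non-numeric feature cell is a load error naming the offending row and
#' column; row order in the file is preserved as sample order.
#'
#' @param path path to a CSV file with a header row.
#' @param label_column optional name of the label column.
#' @param domain_tag tag stored on the returned dataset.
#' @return a [domain_dataset()].
#' @seealso [write_domain_table()]
#' @export
read_domain_table <- function(path, label_column = NULL,
                              domain_tag = "unspecified") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, header = TRUE, check.names = FALSE,
                 colClasses = NA, stringsAsFactors = FALSE)
  if (nrow(df) < 1L || ncol(df) < 1L) stop(sprintf("empty table: %s", path))
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      stop(sprintf("label column '%s' not present in %s", label_column, path))
    }
    labels <- df[[label_column]]
    df <- df[, setdiff(names(df), label_column), drop = FALSE]
    if (ncol(df) < 1L) stop("table has no feature columns besides the labels")
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop(sprintf("non-numeric feature cell at row %d, column '%s'",
                     bad[1], names(df)[j]))
      }
      df[[j]] <- num
    }
    if (anyNA(df[[j]])) {
      stop(sprintf("missing feature value at row %d, column '%s'",
                   which(is.na(df[[j]]))[1], names(df)[j]))
    }
  }
  domain_dataset(as.matrix(df), labels = labels,
                 feature_names = names(df), domain_tag = domain_tag)
}

#' Write a domain dataset to a delimited text file
#'
#' Writes the feature matrix (and, when present, the labels as a final
#' `label` column) as CSV with a header row. Values are serialized at full
#' double precision so that a read/write round trip reproduces the features
#' to machine accuracy and the labels exactly.
#'
#' @param data a [domain_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(data, path) {
  stopifnot(inherits(data, "domain_dataset"))
  feat <- data$features
  nms <- colnames(feat)
  if (is.null(nms)) nms <- paste0("f", seq_len(ncol(feat)))
  cells <- matrix(sprintf("%.17g", feat), nrow = nrow(feat))
  header <- nms
  if (!is.null(data$labels)) {
    cells <- cbind(cells, as.character(data$labels))
    header <- c(header, "label")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(cells, 1, paste, collapse = ","), con)
  invisible(path)
}
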