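# Tabular dataset container and I/O: CSV/ARFF in, report CSV out, and the
# min-max normalisation required by the chi-square quality kernel.

#' Construct an oam_dataset
#'
#' The basic container used throughout: an `n x d` numeric matrix of finite
#' values with feature names and optional 0/1 anomaly labels (1 = anomaly).
#'
#' @param values numeric matrix (rows = records, columns = features), or a
#'   data frame coercible to one.
#' @param feature_names optional character vector of length `d`; defaults to
#'   the column names of `values` or `V1..Vd`.
#' @param labels optional integer/numeric vector in `{0, 1}` of length `n`;
#'   must contain at least one 0.
#' @param name dataset name used in reports.
#' @return an object of class `oam_dataset` with elements `values`,
#'   `feature_names`, `labels`, `name`.
#' @export
oam_dataset <- function(values, feature_names = NULL, labels = NULL,
                        name = "dataset") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("dataset must have at least one row and one column")
  }
  if (!all(is.finite(values))) {
    stop("dataset contains missing or non-finite values")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) {
      feature_names <- paste0("V", seq_len(ncol(values)))
    }
  }
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length does not match number of columns")
  }
  colnames(values) <- feature_names
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values)) {
      stop("labels length does not match number of rows")
    }
    if (!all(labels %in% c(0L, 1L))) {
      stop("labels must be 0 (normal) or 1 (anomaly)")
    }
    if (!any(labels == 0L)) {
      stop("labels must contain at least one normal (0) record")
    }
  }
  structure(list(values = values, feature_names = feature_names,
                 labels = labels, name = name),
            class = "oam_dataset")
}

#' @export
print.oam_dataset <- function(x, ...) {
  cat(sprintf("oam_dataset '%s': %d records x %d features%s\n",
              x$name, nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else
                sprintf(", %d labelled anomalies", sum(x$labels))))
  invisible(x)
}

#' @export
dim.oam_dataset <- function(x) dim(x$values)

#' Read a tabular dataset from CSV or ARFF
#'
#' CSV files must have a header row, comma separators and "." decimals.
#' ARFF files are read with [foreign::read.arff()]; a two-valued nominal
#' class attribute is accepted as the label column. Rows containing missing
#' values are dropped with a message giving the count (`on_missing =
#' "drop"`) or rejected (`on_missing = "error"`).
#'
#' @param path file path.
#' @param label_column optional name of the 0/1 anomaly label column; it is
#'   removed from the feature matrix and stored as `labels`.
#' @param format `"csv"` or `"arff"`; guessed from the file extension by
#'   default.
#' @param on_missing `"drop"` (default) or `"error"`.
#' @return an [oam_dataset()]; the number of dropped rows is attached as
#'   attribute `"dropped_rows"`.
#' @export
load_table <- function(path, label_column = NULL,
                       format = c("auto", "csv", "arff"),
                       on_missing = c("drop", "error")) {
  format <- match.arg(format)
  on_missing <- match.arg(on_missing)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (format == "arff") {
    df <- foreign::read.arff(path)
  } else {
    df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, strip.white = TRUE)
    for (j in seq_along(df)) {
      col <- df[[j]]
      col[col == ""] <- NA_character_
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0L) {
        stop(sprintf("cannot parse cell at row %d, column '%s': '%s'",
                     bad[1L], names(df)[j], col[bad[1L]]))
      }
      df[[j]] <- num
    }
  }
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      stop("label column '", label_column, "' not found")
    }
    lab <- df[[label_column]]
    if (is.factor(lab) || is.character(lab)) {
      lev <- sort(unique(as.character(lab[!is.na(lab)])))
      if (length(lev) != 2L) {
        stop("nominal label column must have exactly two values")
      }
      lab <- as.numeric(match(as.character(lab), lev) - 1L)
    }
    df[[label_column]] <- NULL
    labels <- lab
  }
  mat <- as.matrix(df)
  storage.mode(mat) <- "double"
  keep <- rowSums(!is.finite(mat)) == 0L
  if (!is.null(labels)) keep <- keep & is.finite(labels)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    if (on_missing == "error") {
      stop(dropped, " row(s) contain missing values")
    }
    message("dropped ", dropped, " row(s) with missing values")
    mat <- mat[keep, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[keep]
  }
  if (nrow(mat) == 0L) stop("no complete rows left after dropping missing values")
  if (!is.null(labels) && !all(labels %in% c(0, 1))) {
    bad <- labels[!labels %in% c(0, 1)][1L]
    stop("label column '", label_column, "' has value ", bad,
         " outside {0, 1}")
  }
  ds <- oam_dataset(mat, labels = labels,
                    name = sub("\\.[A-Za-z]+$", "", basename(path)))
  attr(ds, "dropped_rows") <- dropped
  ds
}

#' Write a dataset to CSV
#'
#' Inverse of [load_table()] for CSV: features as columns plus an optional
#' `label` column.
#'
#' @param data an [oam_dataset()].
#' @param path output path.
#' @param label_column name for the label column when labels are present.
#' @export
write_table <- function(data, path, label_column = "label") {
  df <- as.data.frame(data$values)
  if (!is.null(data$labels)) df[[label_column]] <- data$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Min-max normalise a dataset to the unit hypercube
#'
#' Maps every column affinely onto `[0, 1]`; a constant column maps to all
#' zeros. The chi-square quality kernel requires non-negative inputs, so
#' [subspace_quality()] insists on data normalised this way. The per-column
#' minima and ranges are attached as attribute `"ranges"` (a list with
#' `min` and `range`) so out-of-sample query points can be mapped
#' identically with [apply_normalization()].
#'
#' @param data an [oam_dataset()].
#' @return a normalised [oam_dataset()] with attribute `"ranges"`.
#' @export
minmax_normalize <- function(data) {
  X <- data$values
  mins <- apply(X, 2L, min)
  maxs <- apply(X, 2L, max)
  rng <- maxs - mins
  scl <- ifelse(rng > 0, rng, 1)  # constant column -> zeros, not NaN
  Xn <- sweep(sweep(X, 2L, mins, "-"), 2L, scl, "/")
  out <- oam_dataset(Xn, feature_names = data$feature_names,
                     labels = data$labels, name = data$name)
  attr(out, "ranges") <- list(min = mins, range = rng)
  out
}

#' Apply a stored min-max normalisation to new points
#'
#' @param x numeric vector (one point) or matrix of points.
#' @param ranges the `"ranges"` attribute of [minmax_normalize()] output.
#' @return normalised vector or matrix on the same scale as the normalised
#'   dataset.
#' @export
apply_normalization <- function(x, ranges) {
  scl <- ifelse(ranges$range > 0, ranges$range, 1)
  if (is.matrix(x)) {
    sweep(sweep(x, 2L, ranges$min, "-"), 2L, scl, "/")
  } else {
    (x - ranges$min) / scl
  }
}
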