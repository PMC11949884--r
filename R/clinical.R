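#' Clinical feature tables
#'
#' A `clinical_table` bundles a numeric patient-by-feature matrix with a
#' binary disease label: the input to both the causal-discovery and the
#' classification stage. Rows are patients (samples), columns are clinical
#' features such as blood-routine or blood-biochemistry indicators.
#'
#' @param X numeric matrix, one row per sample, named columns.
#' @param y binary (0/1) label vector, one entry per row of `X`.
#' @param label_name name of the disease label.
#' @param sample_ids optional sample identifiers; defaults to row numbers.
#' @param n_dropped number of rows removed during loading (bookkeeping).
#'
#' @return An object of class `clinical_table`: a list with elements `X`,
#'   `y`, `feature_names`, `label_name`, `sample_ids`, `n_dropped`, and
#'   (after [standardize()]) `y_raw` plus centering/scaling attributes.
#' @seealso [read_clinical_table()], [standardize()], [make_dataset()]
#' @export
clinical_table <- function(X, y, label_name = "disease",
                           sample_ids = NULL, n_dropped = 0L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X)))
    stopf("feature names must be unique")
  if (label_name %in% colnames(X))
    stopf("label name %s collides with a feature column", sQuote(label_name))
  if (anyNA(X)) stopf("X must not contain missing values")
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    stopf("length of y (%d) must equal number of rows of X (%d)",
          length(y), nrow(X))
  if (!all(y %in% c(0, 1)))
    stopf("label %s must contain only 0/1 values", sQuote(label_name))
  structure(list(
    X = X, y = y,
    feature_names = colnames(X),
    label_name = label_name,
    sample_ids = sample_ids %||% as.character(seq_len(nrow(X))),
    n_dropped = as.integer(n_dropped)
  ), class = "clinical_table")
}

#' Read a clinical table from CSV
#'
#' Reads a header CSV with one patient per row, numeric feature columns and
#' one binary label column. Complete-case analysis: rows with missing or
#' non-numeric feature entries are dropped, and the count of dropped rows is
#' logged and stored on the returned object.
#'
#' @param path path to a CSV file (UTF-8, `.` decimal separator).
#' @param label_column name of the binary label column.
#' @param id_column optional name of a sample-identifier column.
#' @return A [clinical_table()].
#' @export
read_clinical_table <- function(path, label_column, id_column = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_column %in% names(df))
    stopf("configuration error: label column %s not present in %s",
          sQuote(label_column), path)
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(df))
      stopf("configuration error: id column %s not present", sQuote(id_column))
    ids <- as.character(df[[id_column]])
    df[[id_column]] <- NULL
  }
  ylab <- suppressWarnings(as.numeric(df[[label_column]]))
  if (any(!is.na(ylab) & !ylab %in% c(0, 1)))
    stopf("data error: label column %s contains values other than 0/1",
          sQuote(label_column))
  feats <- setdiff(names(df), label_column)
  Xraw <- suppressWarnings(
    vapply(df[feats], function(col) as.numeric(col), numeric(nrow(df))))
  Xraw <- matrix(Xraw, nrow = nrow(df), dimnames = list(NULL, feats))
  keep <- stats::complete.cases(Xraw) & !is.na(ylab)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    cc_log("read_clinical_table: dropped %d incomplete row(s) of %d",
           n_dropped, nrow(df))
  if (sum(keep) < 10)
    stopf("data error: fewer than 10 usable rows after dropping incomplete cases")
  clinical_table(Xraw[keep, , drop = FALSE], ylab[keep],
                 label_name = label_column,
                 sample_ids = if (is.null(ids)) NULL else ids[keep],
                 n_dropped = n_dropped)
}

#' Standardize a clinical table
#'
#' Transforms every feature column and the label column to zero mean and
#' unit sample variance (unbiased, n-1 denominator). The disease label is
#' standardized because the causal-discovery stage treats it as one more
#' observed variable; the original 0/1 labels are retained in `y_raw` so the
#' classifier keeps binary targets. Zero-variance feature columns are
#' dropped with a warning.
#'
#' @param table a [clinical_table()].
#' @return A `clinical_table` with standardized `X` and `y`, the original
#'   labels in `y_raw`, and `standardized = TRUE`.
#' @export
standardize <- function(table) {
  stopifnot(inherits(table, "clinical_table"))
  X <- table$X
  v <- apply(X, 2L, stats::var)
  zero <- v <= .Machine$double.eps
  if (any(zero)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(colnames(X)[zero], collapse = ", ")), call. = FALSE)
    X <- X[, !zero, drop = FALSE]
  }
  if (ncol(X) == 0L) stopf("no feature column with nonzero variance remains")
  Xs <- scale(X)
  y_raw <- table$y_raw %||% table$y
  if (stats::var(y_raw) <= .Machine$double.eps)
    stopf("label has zero variance: both classes must be present")
  ys <- as.numeric(scale(y_raw))
  out <- table
  out$X <- Xs[, , drop = FALSE]
  attr(out$X, "scaled:center") <- attr(Xs, "scaled:center")
  attr(out$X, "scaled:scale") <- attr(Xs, "scaled:scale")
  out$y <- ys
  out$y_raw <- y_raw
  out$feature_names <- colnames(out$X)
  out$standardized <- TRUE
  out
}

#' @export
print.clinical_table <- function(x, ...) {
  cat(sprintf("Clinical table: %d samples x %d features, label %s\n",
              nrow(x$X), ncol(x$X), sQuote(x$label_name)))
  yr <- x$y_raw %||% x$y
  if (all(yr %in% c(0, 1)))
    cat(sprintf("  prevalence: %.3f", mean(yr)))
  if (isTRUE(x$standardized)) cat("  (standardized)")
  cat("\n")
  if (x$n_dropped > 0)
    cat(sprintf("  %d row(s) dropped on load\n", x$n_dropped))
  invisible(x)
}

#' Write a clinical table to CSV
#'
#' Inverse of [read_clinical_table()]: features plus the (raw, binary) label
#' column; standardization is not undone.
#'
#' @param table a [clinical_table()].
#' @param path output CSV path.
#' @export
write_clinical_table <- function(table, path) {
  stopifnot(inherits(table, "clinical_table"))
  df <- as.data.frame(table$X)
  df[[table$label_name]] <- table$y_raw %||% table$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
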