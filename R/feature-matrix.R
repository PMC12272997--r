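#' Construct a feature matrix
#'
#' A `feature_matrix` is the basic data container of the package: an
#' `n x d` numeric block of `n` samples by `d` named features, e.g. 90
#' brain-region (ROI) volumes, SNP dosages, or gene-expression values.
#' All entries must be finite; missing data are rejected rather than
#' imputed, mirroring the usual SCCA preprocessing convention that
#' incomplete samples are excluded upstream.
#'
#' @param values numeric matrix (samples in rows, features in columns).
#' @param sample_ids character vector of row identifiers; defaults to
#'   `rownames(values)` or `"s1"..."sn"`.
#' @param feature_names character vector of column names; defaults to
#'   `colnames(values)` or `"f1"..."fd"`.
#' @param standardized logical flag recording whether columns have been
#'   centered/scaled by [standardize()].
#' @return An object of class `feature_matrix` with fields `values`,
#'   `sample_ids`, `feature_names`, `standardized`.
#' @examples
#' fm <- feature_matrix(matrix(rnorm(12), 4, 3))
#' dim(fm)
#' @export
feature_matrix <- function(values, sample_ids = NULL, feature_names = NULL,
                           standardized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_validation("`values` must be a numeric matrix")
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    abort_validation(sprintf(
      "non-finite value at row %d, column %d; missing data must be handled upstream",
      bad[1L], bad[2L]
    ))
  }
  n <- nrow(values)
  d <- ncol(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(d))
  }
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  if (length(sample_ids) != n) {
    abort_validation(sprintf(
      "%d sample ids for %d rows", length(sample_ids), n
    ))
  }
  if (length(feature_names) != d) {
    abort_validation(sprintf(
      "%d feature names for %d columns", length(feature_names), d
    ))
  }
  if (anyDuplicated(feature_names)) {
    dup <- feature_names[duplicated(feature_names)][1L]
    abort_validation(sprintf("duplicate feature name '%s'", dup))
  }
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1L]
    abort_validation(sprintf("duplicate sample id '%s'", dup))
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values, sample_ids = sample_ids,
         feature_names = feature_names, standardized = isTRUE(standardized)),
    class = "feature_matrix"
  )
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d samples x %d features%s\n",
    nrow(x$values), ncol(x$values),
    if (x$standardized) " (standardized)" else ""
  ))
  invisible(x)
}

#' Read a delimited sample-by-feature matrix
#'
#' Expects a header row of feature names with the first column holding
#' sample identifiers; every remaining cell must be numeric and
#' non-missing. Cells that do not parse are reported with their row and
#' column so offending inputs can be fixed upstream.
#'
#' @param path file to read.
#' @param delimiter field separator, `","` (default) or `"\t"`.
#' @return A [feature_matrix()] with `standardized = FALSE`; row and
#'   column order is preserved from the file.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, delimiter = ",") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.table(
    path, header = TRUE, sep = delimiter, colClasses = "character",
    check.names = FALSE, quote = "\"", comment.char = "", strip.white = TRUE
  )
  if (ncol(df) < 2L) {
    abort_validation(sprintf(
      "%s: need a sample-id column plus at least one feature column", path
    ))
  }
  ids <- df[[1L]]
  feats <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), length(feats))
  for (j in seq_along(feats)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | col %in% c("", "NA", "NaN"))
    if (length(bad)) {
      abort_validation(sprintf(
        "%s: non-numeric or missing value '%s' at data row %d, column '%s'",
        path, col[bad[1L]], bad[1L], feats[j]
      ))
    }
    vals[, j] <- num
  }
  feature_matrix(vals, sample_ids = ids, feature_names = feats)
}

#' Write a feature matrix to delimited text
#'
#' Inverse of [read_matrix()]: header row of feature names, first column
#' `sample_id`, `.` decimal separator, full double precision.
#'
#' @param m a [feature_matrix()].
#' @param path output file.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, delimiter = ",") {
  stopifnot(inherits(m, "feature_matrix"))
  df <- data.frame(sample_id = m$sample_ids, check.names = FALSE)
  vals <- m$values
  df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  utils::write.table(
    df, path, sep = delimiter, quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}

#' Column-standardize a feature matrix
#'
#' Centers every column to mean zero and scales columns with nonzero
#' variance to unit sample standard deviation (denominator `n - 1`,
#' matching the Pearson-correlation convention). Constant columns are
#' centered only, so no division by zero can occur. Idempotent.
#'
#' @param m a [feature_matrix()], or a [data_block()] whose X and Y
#'   blocks are standardized jointly.
#' @return The standardized object with `standardized = TRUE`.
#' @export
standardize <- function(m) UseMethod("standardize")

#' @export
standardize.feature_matrix <- function(m) {
  v <- m$values
  if (nrow(v) < 2L) {
    abort_validation("standardize needs at least 2 samples")
  }
  ctr <- colMeans(v)
  v <- sweep(v, 2L, ctr, "-")
  sds <- sqrt(colSums(v^2) / (nrow(v) - 1L))
  nz <- sds > 0
  if (any(nz)) v[, nz] <- sweep(v[, nz, drop = FALSE], 2L, sds[nz], "/")
  feature_matrix(v, m$sample_ids, m$feature_names, standardized = TRUE)
}
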