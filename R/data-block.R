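#' Assemble an aligned multi-block data set
#'
#' Joins one imaging block `X` with `M` genetic blocks `Y_m` on their
#' shared sample identifiers (inner join, preserving the order of `X`),
#' optionally attaching a binary diagnosis vector (case = 1, e.g. AD;
#' control = 0, e.g. MCI). All `Y` blocks must have the same number of
#' features `q`: the multi-task solver treats feature `j` of every task
#' as one row of the joint weight matrix `V`, so unequal widths are a
#' structural error, not something to pad over.
#'
#' @param X a [feature_matrix()] — the shared (imaging) block.
#' @param Ys list of [feature_matrix()] objects — the task blocks.
#' @param labels optional 0/1 vector, aligned with `X`'s samples (it is
#'   subset with the join).
#' @return An object of class `data_block` with fields `X`, `Y` (list),
#'   `labels`, `M`.
#' @export
assemble_block <- function(X, Ys, labels = NULL) {
  stopifnot(inherits(X, "feature_matrix"))
  if (inherits(Ys, "feature_matrix")) Ys <- list(Ys)
  if (!length(Ys) || !all(vapply(Ys, inherits, TRUE, "feature_matrix"))) {
    abort_validation("`Ys` must be a non-empty list of feature_matrix objects")
  }
  qs <- vapply(Ys, function(y) ncol(y$values), 0L)
  if (length(unique(qs)) != 1L) {
    abort_validation(sprintf(
      "all Y blocks must have the same feature count; got %s",
      paste(qs, collapse = ", ")
    ))
  }
  if (!is.null(labels)) {
    labels <- check_binary_labels(labels, nrow(X$values))
    names(labels) <- X$sample_ids
  }

  keep <- X$sample_ids
  for (y in Ys) keep <- keep[keep %in% y$sample_ids]
  if (!length(keep)) {
    abort_validation("no samples shared by all blocks")
  }
  sub <- function(fm, ids) {
    feature_matrix(fm$values[match(ids, fm$sample_ids), , drop = FALSE],
                   ids, fm$feature_names, fm$standardized)
  }
  X <- sub(X, keep)
  Ys <- lapply(Ys, sub, ids = keep)
  if (!is.null(labels)) labels <- unname(labels[keep])
  if (is.null(names(Ys)) || any(!nzchar(names(Ys)))) {
    names(Ys) <- paste0("Y", seq_along(Ys))
  }
  structure(
    list(X = X, Y = Ys, labels = labels, M = length(Ys)),
    class = "data_block"
  )
}

#' @export
print.data_block <- function(x, ...) {
  cat(sprintf(
    "<data_block> n=%d samples, X: %d features, %d task block(s) of %d features%s\n",
    nrow(x$X$values), ncol(x$X$values), x$M, ncol(x$Y[[1L]]$values),
    if (!is.null(x$labels)) sprintf(", labels (%d cases)", sum(x$labels)) else ""
  ))
  invisible(x)
}

#' @export
standardize.data_block <- function(m) {
  m$X <- standardize(m$X)
  m$Y <- lapply(m$Y, standardize)
  m
}

is_standardized <- function(block) {
  block$X$standardized && all(vapply(block$Y, `[[`, TRUE, "standardized"))
}
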