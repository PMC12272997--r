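#' Structured matrix norms
#'
#' `l21_norm` is the row-wise group norm \eqn{\|W\|_{2,1} = \sum_i
#' \|W_{i,.}\|_2}: each row collects one feature's weights across all
#' tasks, so penalizing it zeroes whole features jointly. `l11_norm` is
#' the plain entry-wise \eqn{\|W\|_{1,1} = \sum_{ij} |w_{ij}|}, giving
#' element-level sparsity within tasks.
#'
#' @param W numeric matrix (a vector is treated as a one-column matrix).
#' @return A single nonnegative number.
#' @examples
#' l21_norm(rbind(c(3, 4), c(0, 0)))  # 5
#' l11_norm(rbind(c(1, -2), c(3, 0))) # 6
#' @export
l21_norm <- function(W) {
  W <- as.matrix(W)
  sum(sqrt(rowSums(W^2)))
}

#' @rdname l21_norm
#' @export
l11_norm <- function(W) {
  sum(abs(W))
}

# Half-quadratic reweighting diagonals. The sparsity norms are handled
# by the standard smooth surrogate: at the current iterate W the term
# lambda * ||W||_{2,1} is majorized by the quadratic
# lambda * sum_m v_m' D v_m with D = diag(1 / (2 max(||W_i.||, eps))),
# refreshed every sweep; likewise 1/(2 max(|v_j|, eps)) for the 1,1 norm.
# eps guards zero rows/entries and caps the diagonal at 1/(2 eps).

#' Reweighting diagonal for the L2,1 penalty
#'
#' Returns the per-row diagonal entries `1 / (2 * max(||W_i,.||_2, eps))`
#' used to replace the nonsmooth group penalty with a quadratic term in
#' the alternating solver. Rows with norm below `epsilon` are capped at
#' `1/(2*epsilon)` so the diagonal stays finite.
#'
#' @param W numeric matrix of current weights (features x tasks).
#' @param epsilon positive guard, default `1e-6`.
#' @return Numeric vector with one entry per row of `W`.
#' @export
reweight_diag_21 <- function(W, epsilon = 1e-6) {
  check_scalar(epsilon, "epsilon", lower = 0, strict = TRUE)
  W <- as.matrix(W)
  1 / (2 * pmax(sqrt(rowSums(W^2)), epsilon))
}

#' Reweighting diagonal for the L1,1 penalty
#'
#' Per-entry diagonal `1 / (2 * max(|v_j|, eps))` for one task's weight
#' vector.
#'
#' @param v numeric vector of current weights for one task.
#' @param epsilon positive guard, default `1e-6`.
#' @return Numeric vector of the same length as `v`.
#' @export
reweight_diag_11 <- function(v, epsilon = 1e-6) {
  check_scalar(epsilon, "epsilon", lower = 0, strict = TRUE)
  1 / (2 * pmax(abs(v), epsilon))
}
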