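#' Solver hyperparameters
#'
#' Collects the penalty strengths and numerical controls of the
#' alternating solver. `lambda_v1`/`lambda_u1` weight the L2,1
#' (feature-level, cross-task) sparsity of `V`/`U`, `lambda_v2` the
#' L1,1 (entry-level) sparsity of `V`, and `lambda_v3`/`lambda_u2` the
#' per-column orthogonality penalties `||w w' - I||_F^2` that discourage
#' redundant, mutually correlated selections. The defaults are the
#' combination selected by exhaustive grid search over
#' \{0.001, 0.01, 0.1, 1\} in the motivating imaging-genetics
#' application; they are sensible starting values at unit-variance
#' scaling, not universal constants.
#'
#' `gamma_u`/`gamma_v` add an optional quadratic pull on the score norms
#' inside the linear systems; they default to 0 because the unit-score
#' constraints are enforced exactly by rescaling after every update.
#'
#' @param lambda_v1,lambda_v2,lambda_v3,lambda_u1,lambda_u2 nonnegative
#'   penalty strengths (see Description).
#' @param gamma_u,gamma_v nonnegative scale-constraint multipliers,
#'   default 0.
#' @param epsilon positive guard in the reweighting diagonals
#'   (default `1e-6`).
#' @param tol convergence threshold on the maximum absolute weight
#'   change per sweep (default `1e-5`).
#' @param max_iter maximum number of alternating sweeps (default 100).
#' @param seed integer seed used only by randomized initialization.
#' @return A list of class `hyperparams`.
#' @export
hyperparams <- function(lambda_v1 = 0.001, lambda_v2 = 0.001,
                        lambda_v3 = 0.01, lambda_u1 = 0.1, lambda_u2 = 0.1,
                        gamma_u = 0, gamma_v = 0, epsilon = 1e-6,
                        tol = 1e-5, max_iter = 100L, seed = 1L) {
  for (nm in c("lambda_v1", "lambda_v2", "lambda_v3", "lambda_u1",
               "lambda_u2", "gamma_u", "gamma_v")) {
    check_scalar(get(nm), nm, lower = 0)
  }
  check_scalar(epsilon, "epsilon", lower = 0, strict = TRUE)
  check_scalar(tol, "tol", lower = 0, strict = TRUE)
  check_scalar(max_iter, "max_iter", lower = 1, integerish = TRUE)
  structure(
    list(lambda_v1 = lambda_v1, lambda_v2 = lambda_v2, lambda_v3 = lambda_v3,
         lambda_u1 = lambda_u1, lambda_u2 = lambda_u2,
         gamma_u = gamma_u, gamma_v = gamma_v, epsilon = epsilon,
         tol = tol, max_iter = as.integer(max_iter), seed = seed),
    class = "hyperparams"
  )
}

as_hyperparams <- function(hp) {
  if (inherits(hp, "hyperparams")) return(hp)
  do.call(hyperparams, hp)
}
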