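# Alternating reweighted-least-squares solver for multi-task sparse CCA
# with per-column orthogonality penalties (MTOSCCA), and the penalized
# multi-task SCCA baseline obtained by switching the orthogonality
# penalties off.
#
# Objective (per task m = 1..M, on standardized blocks):
#   ||X u_m - Y_m v_m||^2 + lambda_v3 ||v_m v_m' - I||_F^2
#                         + lambda_u2 ||u_m u_m' - I||_F^2
# + lambda_v1 ||V||_{2,1} + lambda_v2 ||V||_{1,1} + lambda_u1 ||U||_{2,1}
#   s.t. ||X u_m|| = ||Y_m v_m|| = 1.
#
# A note on the update equations. The closed-form updates this scheme is
# based on are sometimes quoted with two typographical slips: the Gram
# matrix Y'Y appearing twice in the v-system (once bare, once with the
# (gamma+1) factor), and a u-system whose right-hand side X'Y_m is p x q
# rather than a vector. Re-deriving the stationarity condition of the
# surrogate objective gives the consistent form implemented here:
#   [ (1+gamma_v) Y'Y + lambda_v1 D_v1 + lambda_v2 D_v2
#     + 2 lambda_v3 (v v' - I) ] v_new = Y' X u            (v-step)
#   [ (1+gamma_u) X'X + lambda_u1 D_u1
#     + 2 lambda_u2 (u u' - I) ] u_new = X' Y_m v_m        (u-step)
# with the sparsity diagonals D from reweight_diag_21()/reweight_diag_11()
# and the orthogonality gradient linearized at the previous iterate so
# each subproblem stays a linear solve.

# Symmetrize and solve A x = b; if the solve fails (q can exceed n, so
# the Gram matrix alone is rank-deficient), add an escalating ridge of
# 1e-8 * trace(A)/dim before giving up with a condition estimate.
solve_stabilized <- function(A, b) {
  A <- (A + t(A)) / 2
  try_solve <- function(M) {
    out <- tryCatch(solve(M, b), error = function(e) NULL)
    if (!is.null(out) && all(is.finite(out))) out else NULL
  }
  sol <- try_solve(A)
  if (!is.null(sol)) return(sol)
  ridge <- 1e-8 * sum(diag(A)) / nrow(A)
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-8
  for (k in 1:4) {
    sol <- try_solve(A + diag(ridge, nrow(A)))
    if (!is.null(sol)) return(sol)
    ridge <- ridge * 1e4
  }
  abort_numerical(sprintf(
    "linear system is singular even after ridge stabilization (kappa ~ %.3g)",
    kappa(A, exact = FALSE)
  ))
}

#' Single task-weight update (v-step)
#'
#' Solves the regularized least-squares system for one task's genetic
#' weight vector with the imaging weights held fixed: the Gram matrix of
#' `Y_m` plus the sparsity reweighting diagonals (computed at the current
#' iterate) plus the linearized orthogonality term, against the
#' right-hand side `Y_m' X u_m`. Exposed mainly for testing and
#' didactics; [fit_mtoscca()] calls the same computation with cached
#' Gram matrices.
#'
#' @param X n x p imaging matrix (standardized).
#' @param Y_m n x q task matrix (standardized).
#' @param u_m current length-p imaging weights for this task.
#' @param v_prev current length-q weights for this task (linearization
#'   point for the orthogonality and L1,1 terms).
#' @param V_prev current q x M weight matrix (for the cross-task L2,1
#'   diagonal).
#' @param hp a [hyperparams()] object.
#' @return Length-q solution vector (not yet rescaled to the unit-score
#'   constraint).
#' @export
update_v <- function(X, Y_m, u_m, v_prev, V_prev, hp) {
  hp <- as_hyperparams(hp)
  update_v_core(crossprod(Y_m), crossprod(Y_m, X %*% u_m), v_prev, V_prev, hp)
}

update_v_core <- function(YtY, rhs, v_prev, V_prev, hp) {
  A <- (1 + hp$gamma_v) * YtY
  diag(A) <- diag(A) +
    hp$lambda_v1 * reweight_diag_21(V_prev, hp$epsilon) +
    hp$lambda_v2 * reweight_diag_11(v_prev, hp$epsilon)
  if (hp$lambda_v3 > 0) {
    A <- A + (2 * hp$lambda_v3) * tcrossprod(v_prev)
    diag(A) <- diag(A) - 2 * hp$lambda_v3
  }
  drop(solve_stabilized(A, rhs))
}

#' Single imaging-weight update (u-step)
#'
#' Mirror image of [update_v()]: solves for one task's imaging weight
#' vector with the genetic weights fixed, right-hand side `X' Y_m v_m`.
#'
#' @inheritParams update_v
#' @param v_m current length-q task weights.
#' @param u_prev current length-p weights for this task.
#' @param U_prev current p x M imaging weight matrix.
#' @return Length-p solution vector (not yet rescaled).
#' @export
update_u <- function(X, Y_m, v_m, u_prev, U_prev, hp) {
  hp <- as_hyperparams(hp)
  update_u_core(crossprod(X), crossprod(X, Y_m %*% v_m), u_prev, U_prev, hp)
}

update_u_core <- function(XtX, rhs, u_prev, U_prev, hp) {
  A <- (1 + hp$gamma_u) * XtX
  diag(A) <- diag(A) + hp$lambda_u1 * reweight_diag_21(U_prev, hp$epsilon)
  if (hp$lambda_u2 > 0) {
    A <- A + (2 * hp$lambda_u2) * tcrossprod(u_prev)
    diag(A) <- diag(A) - 2 * hp$lambda_u2
  }
  drop(solve_stabilized(A, rhs))
}

#' Rescale a weight vector to the unit-score constraint
#'
#' Divides `w` by `||Z w||_2` so the projected score has unit Euclidean
#' norm, enforcing the scale constraint of the model exactly after each
#' linear-solve update.
#'
#' @param w weight vector.
#' @param Z data matrix whose projection is constrained.
#' @return Rescaled copy of `w`.
#' @export
rescale_to_constraint <- function(w, Z) {
  nrm <- sqrt(sum((Z %*% w)^2))
  if (!is.finite(nrm) || nrm < 1e-12) {
    abort_numerical("degenerate direction: ||Z w|| below 1e-12, cannot rescale")
  }
  w / nrm
}

# ||w w' - I_d||_F^2 = (sum w^2)^2 - 2 sum w^2 + d, d = length(w)
orth_penalty <- function(w) {
  s <- sum(w^2)
  s^2 - 2 * s + length(w)
}

#' Full penalized objective
#'
#' Evaluates the MTOSCCA objective at a given weight set: per-task
#' residuals `||X u_m - Y_m v_m||^2` plus the per-column orthogonality
#' penalties (Frobenius norm) plus the global L2,1/L1,1 sparsity terms.
#'
#' @param block a [data_block()] (standardized for meaningful values).
#' @param weights list with elements `U` (p x M) and `V` (q x M).
#' @param hp a [hyperparams()] object.
#' @return Single nonnegative number.
#' @export
mtoscca_objective <- function(block, weights, hp) {
  hp <- as_hyperparams(hp)
  U <- as.matrix(weights$U)
  V <- as.matrix(weights$V)
  Xv <- block$X$values
  total <- 0
  for (m in seq_len(block$M)) {
    r <- Xv %*% U[, m] - block$Y[[m]]$values %*% V[, m]
    total <- total + sum(r^2) +
      hp$lambda_v3 * orth_penalty(V[, m]) +
      hp$lambda_u2 * orth_penalty(U[, m])
  }
  total + hp$lambda_v1 * l21_norm(V) + hp$lambda_v2 * l11_norm(V) +
    hp$lambda_u1 * l21_norm(U)
}

#' Fit the orthogonality-penalized multi-task sparse CCA model
#'
#' Alternates, for each task `m`, a regularized linear solve for `v_m`
#' followed by rescaling to `||Y_m v_m|| = 1`, then the analogous solve
#' and rescale for `u_m`, refreshing the sparsity reweighting diagonals
#' and the orthogonality linearization point from the current iterate at
#' every step. Iteration stops when the largest absolute change over all
#' weight entries falls below `hp$tol`, or after `hp$max_iter` sweeps.
#'
#' The sign of each `(u_m, v_m)` pair is canonicalized at return (largest
#' |entry| of `u_m` made positive); this leaves both the objective and the
#' canonical correlations unchanged but makes runs bit-reproducible.
#'
#' @param block a [data_block()]; standardized internally if it is not
#'   already (columns to mean 0, unit sample SD).
#' @param hp a [hyperparams()] object.
#' @param init `"svd"` (default): start each task at the leading
#'   singular-vector pair of the cross-covariance `X' Y_m`, the
#'   standard warm start for alternating SCCA solvers — deterministic
#'   and inside the basin of the dominant shared factor. `"ones"`:
#'   all-ones start (deterministic but can land in a spurious basin
#'   when the reweighted penalties self-reinforce). `"random"`:
#'   standard-normal start seeded by `hp$seed`.
#' @return An object of class `scca_fit`: list with `weights` (list
#'   `U`, `V` carrying feature names), `objective_trace`, `n_iter`,
#'   `converged`, `ccc` (per-task canonical correlation at the
#'   solution), `solver`, and the `hp` used.
#' @examples
#' sim <- simulate_block(sim_config(n = 60, p = 10, q = 15, seed = 7))
#' fit <- fit_mtoscca(sim$block, hyperparams(max_iter = 50))
#' fit$ccc
#' @export
fit_mtoscca <- function(block, hp = hyperparams(),
                        init = c("svd", "ones", "random")) {
  init <- match.arg(init)
  fit_scca_impl(block, as_hyperparams(hp), init, solver = "mtoscca")
}

#' Fit the multi-task sparse CCA baseline (no orthogonality penalty)
#'
#' Identical machinery to [fit_mtoscca()] with `lambda_v3 = lambda_u2 =
#' 0`: the structured-sparsity penalized multi-task SCCA whose
#' constraint bounds are realized in Lagrangian (penalized) form. Used
#' as the comparison point that isolates the contribution of the
#' orthogonality penalties.
#'
#' @inheritParams fit_mtoscca
#' @return An `scca_fit`, with `solver = "mtscca"`.
#' @export
fit_mtscca <- function(block, hp = hyperparams(),
                       init = c("svd", "ones", "random")) {
  init <- match.arg(init)
  hp <- as_hyperparams(hp)
  hp$lambda_v3 <- 0
  hp$lambda_u2 <- 0
  fit_scca_impl(block, hp, init, solver = "mtscca")
}

fit_scca_impl <- function(block, hp, init, solver) {
  stopifnot(inherits(block, "data_block"))
  if (!is_standardized(block)) block <- standardize(block)
  Xv <- block$X$values
  M <- block$M
  p <- ncol(Xv)
  q <- ncol(block$Y[[1L]]$values)

  XtX <- crossprod(Xv)
  YtY <- lapply(block$Y, function(y) crossprod(y$values))
  XtY <- lapply(block$Y, function(y) crossprod(Xv, y$values))  # p x q

  if (init == "svd") {
    U <- matrix(0, p, M)
    V <- matrix(0, q, M)
    for (m in seq_len(M)) {
      sv <- svd(XtY[[m]], nu = 1L, nv = 1L)
      U[, m] <- sv$u
      V[, m] <- sv$v
    }
  } else if (init == "ones") {
    U <- matrix(1, p, M)
    V <- matrix(1, q, M)
  } else {
    U <- with_seed(hp$seed, matrix(stats::rnorm(p * M), p, M))
    V <- with_seed(hp$seed + 1L, matrix(stats::rnorm(q * M), q, M))
  }
  for (m in seq_len(M)) {
    U[, m] <- rescale_to_constraint(U[, m], Xv)
    V[, m] <- rescale_to_constraint(V[, m], block$Y[[m]]$values)
  }

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(hp$max_iter)) {
    U_old <- U
    V_old <- V
    for (m in seq_len(M)) {
      v_new <- update_v_core(YtY[[m]], drop(crossprod(XtY[[m]], U[, m])),
                             V[, m], V, hp)
      V[, m] <- rescale_to_constraint(v_new, block$Y[[m]]$values)
      u_new <- update_u_core(XtX, drop(XtY[[m]] %*% V[, m]), U[, m], U, hp)
      U[, m] <- rescale_to_constraint(u_new, Xv)
    }
    obj <- mtoscca_objective(block, list(U = U, V = V), hp)
    if (!is.finite(obj)) {
      abort_numerical(paste(
        "objective diverged to a non-finite value;",
        "try smaller lambda_v3/lambda_u2 or check input scaling"
      ))
    }
    trace <- c(trace, obj)
    delta <- max(abs(U - U_old), abs(V - V_old))
    if (delta < hp$tol) {
      converged <- TRUE
      break
    }
  }

  # canonical joint sign: flip (u_m, v_m) together so the largest-|entry|
  # coordinate of u_m is positive (objective- and CCC-preserving)
  for (m in seq_len(M)) {
    s <- sign(U[which.max(abs(U[, m])), m])
    if (s < 0) {
      U[, m] <- -U[, m]
      V[, m] <- -V[, m]
    }
  }

  ccc <- vapply(seq_len(M), function(m) {
    ccc(Xv, U[, m], block$Y[[m]]$values, V[, m])
  }, 0)

  rownames(U) <- block$X$feature_names
  colnames(U) <- colnames(V) <- names(block$Y)
  task_names <- lapply(block$Y, `[[`, "feature_names")
  # V's rows only have a single shared labelling when the tasks share a
  # feature vocabulary; otherwise names live in feature_names$tasks
  if (length(unique(task_names)) == 1L) {
    rownames(V) <- task_names[[1L]]
  }

  structure(
    list(weights = list(U = U, V = V), objective_trace = trace,
         n_iter = iter, converged = converged, ccc = ccc,
         solver = solver, hp = hp,
         feature_names = list(X = block$X$feature_names,
                              tasks = task_names)),
    class = "scca_fit"
  )
}

#' @export
print.scca_fit <- function(x, ...) {
  cat(sprintf(
    "<scca_fit:%s> %d sweep(s)%s, objective %.6g\n  CCC: %s\n",
    x$solver, x$n_iter, if (x$converged) " (converged)" else " (max_iter hit)",
    utils::tail(x$objective_trace, 1L),
    paste(sprintf("%.4f", x$ccc), collapse = ", ")
  ))
  invisible(x)
}

#' Write fitted weights as tidy CSV
#'
#' Serializes a fitted weight set as rows of `feature_name, task_index,
#' weight` per block (`block` column distinguishes the imaging `U` from
#' the task `V` weights).
#'
#' @param fit an `scca_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(fit, path) {
  stopifnot(inherits(fit, "scca_fit"))
  U <- fit$weights$U
  V <- fit$weights$V
  v_names <- unlist(fit$feature_names$tasks, use.names = FALSE)
  rows <- rbind(
    data.frame(block = "U", feature_name = rep(rownames(U), ncol(U)),
               task_index = rep(seq_len(ncol(U)), each = nrow(U)),
               weight = as.vector(U)),
    data.frame(block = "V", feature_name = v_names,
               task_index = rep(seq_len(ncol(V)), each = nrow(V)),
               weight = as.vector(V))
  )
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
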