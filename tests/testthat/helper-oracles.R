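# Independent oracles, written as plain scalar loops straight from the
# defining formulas. They deliberately share no code with the package
# internals they check.

# v-step system assembled entry by entry from the stationarity condition
oracle_update_v <- function(X, Y, u, v_prev, V_prev, hp) {
  q <- ncol(Y)
  A <- matrix(0, q, q)
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      gram <- sum(Y[, i] * Y[, j])
      A[i, j] <- (1 + hp$gamma_v) * gram +
        2 * hp$lambda_v3 * (v_prev[i] * v_prev[j] - (i == j))
      if (i == j) {
        rn <- max(sqrt(sum(V_prev[i, ]^2)), hp$epsilon)
        A[i, j] <- A[i, j] + hp$lambda_v1 / (2 * rn) +
          hp$lambda_v2 / (2 * max(abs(v_prev[i]), hp$epsilon))
      }
    }
  }
  b <- as.numeric(t(Y) %*% (X %*% u))
  solve(A, b)
}

oracle_update_u <- function(X, Y, v, u_prev, U_prev, hp) {
  p <- ncol(X)
  A <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      A[i, j] <- (1 + hp$gamma_u) * sum(X[, i] * X[, j]) +
        2 * hp$lambda_u2 * (u_prev[i] * u_prev[j] - (i == j))
      if (i == j) {
        rn <- max(sqrt(sum(U_prev[i, ]^2)), hp$epsilon)
        A[i, j] <- A[i, j] + hp$lambda_u1 / (2 * rn)
      }
    }
  }
  b <- as.numeric(t(X) %*% (Y %*% v))
  solve(A, b)
}

# AUC by exhaustive case-control pair counting (ties count one half)
oracle_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}
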