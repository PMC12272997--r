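test_that("update_v and update_u match the loop-assembled dense oracle", {
  hp <- hyperparams(lambda_v1 = 0.1, lambda_v2 = 0.1, lambda_v3 = 0.1,
                    lambda_u1 = 0.2, lambda_u2 = 0.15, gamma_u = 0.3,
                    gamma_v = 0.2)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 12; p <- 5; q <- 4
      X <- matrix(rnorm(n * p), n, p)
      Y <- matrix(rnorm(n * q), n, q)
      u <- rnorm(p); v_prev <- rnorm(q)
      V_prev <- cbind(v_prev, rnorm(q))
      u_prev <- rnorm(p)
      U_prev <- cbind(u_prev, rnorm(p))
    })
    expect_lt(max(abs(update_v(X, Y, u, v_prev, V_prev, hp) -
                        oracle_update_v(X, Y, u, v_prev, V_prev, hp))), 1e-8)
    expect_lt(max(abs(update_u(X, Y, v_prev, u_prev, U_prev, hp) -
                        oracle_update_u(X, Y, v_prev, u_prev, U_prev, hp))), 1e-8)
  }
})

test_that("penalty-free updates reduce to least squares", {
  hp0 <- hyperparams(0, 0, 0, 0, 0)
  withr::with_seed(3, {
    n <- 20; p <- 4; q <- 5
    X <- matrix(rnorm(n * p), n, p)
    u <- rnorm(p)
    # orthonormal-column Y: v = Y' X u
    Yo <- qr.Q(qr(matrix(rnorm(n * q), n, q)))
    v0 <- rep(0.5, q)
    expect_equal(update_v(X, Yo, u, v0, cbind(v0), hp0),
                 as.numeric(t(Yo) %*% X %*% u), tolerance = 1e-10)
    # general Y: ordinary least squares of Xu on Y
    Y <- matrix(rnorm(n * q), n, q)
    ols <- as.numeric(qr.coef(qr(Y), X %*% u))
    expect_equal(update_v(X, Y, u, v0, cbind(v0), hp0), ols,
                 tolerance = 1e-8)
    # and symmetrically for u
    v <- rnorm(q)
    u0 <- rep(1, p)
    ols_u <- as.numeric(qr.coef(qr(X), Y %*% v))
    expect_equal(update_u(X, Y, v, u0, cbind(u0), hp0), ols_u,
                 tolerance = 1e-8)
  })
})

test_that("rescale_to_constraint normalizes the projected score", {
  withr::with_seed(5, {
    Z <- matrix(rnorm(40), 10, 4)
    w <- rnorm(4)
  })
  r <- rescale_to_constraint(w, Z)
  expect_equal(sqrt(sum((Z %*% r)^2)), 1, tolerance = 1e-12)
  expect_equal(rescale_to_constraint(r, Z), r, tolerance = 1e-12)
  expect_equal(rescale_to_constraint(2 * r, Z), r, tolerance = 1e-12)
  expect_error(rescale_to_constraint(rep(0, 4), Z), "degenerate")
})

test_that("mtoscca_objective matches closed forms and a brute-force sum", {
  blk <- make_block(n = 20, p = 3, q = 4, seed = 11)
  hp <- hyperparams(0, 0, 1, 0, 1)
  zero <- list(U = matrix(0, 3, 2), V = matrix(0, 4, 2))
  # each ||0*0' - I_d||_F^2 contributes d; residual 0: 2*(4 + 3) = 14
  expect_equal(mtoscca_objective(blk, zero, hp), 14)

  hp2 <- hyperparams(0.3, 0.2, 0.5, 0.4, 0.6)
  W <- withr::with_seed(12, list(U = matrix(rnorm(6), 3, 2),
                                 V = matrix(rnorm(8), 4, 2)))
  brute <- 0
  for (m in 1:2) {
    r <- blk$X$values %*% W$U[, m] - blk$Y[[m]]$values %*% W$V[, m]
    brute <- brute + sum(r^2)
    Iv <- diag(4); Iu <- diag(3)
    brute <- brute + 0.5 * sum((W$V[, m] %*% t(W$V[, m]) - Iv)^2)
    brute <- brute + 0.6 * sum((W$U[, m] %*% t(W$U[, m]) - Iu)^2)
  }
  brute <- brute + 0.3 * l21_norm(W$V) + 0.2 * l11_norm(W$V) +
    0.4 * l21_norm(W$U)
  expect_equal(mtoscca_objective(blk, W, hp2), brute, tolerance = 1e-12)

  # exact fit with all penalties off scores zero: plant Xu as a Y column
  withr::with_seed(13, {
    Xm <- matrix(rnorm(45), 15, 3)
    u <- rnorm(3)
    Ym <- cbind(Xm %*% u, matrix(rnorm(30), 15, 2))
  })
  blk_exact <- assemble_block(
    feature_matrix(Xm), list(feature_matrix(Ym, feature_names = paste0("g", 1:3)),
                             feature_matrix(Ym, feature_names = paste0("h", 1:3)))
  )
  v <- c(1, 0, 0)
  expect_equal(mtoscca_objective(blk_exact, list(U = cbind(u, u), V = cbind(v, v)),
                                 hyperparams(0, 0, 0, 0, 0)), 0)
})

test_that("fits are deterministic and the baseline is the exact reduction", {
  blk <- make_block(n = 40, p = 6, q = 8, seed = 21)
  f1 <- fit_mtoscca(blk, hyperparams())
  f2 <- fit_mtoscca(blk, hyperparams())
  expect_identical(f1$weights, f2$weights)

  hp0 <- hyperparams()
  hp0$lambda_v3 <- 0
  hp0$lambda_u2 <- 0
  a <- fit_mtoscca(blk, hp0)
  b <- fit_mtscca(blk, hyperparams())
  expect_identical(a$weights, b$weights)
  expect_identical(a$objective_trace, b$objective_trace)

  r1 <- fit_mtoscca(blk, hyperparams(seed = 9L), init = "random")
  r2 <- fit_mtoscca(blk, hyperparams(seed = 9L), init = "random")
  expect_identical(r1$weights, r2$weights)
})

test_that("objective descends and constraints hold on random blocks", {
  for (seed in 1:8) {
    blk <- make_block(n = 40, p = 7, q = 9, seed = 100 + seed)
    fit <- fit_mtoscca(blk, hyperparams())
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-6 * (1 + abs(tr[1]))),
                info = sprintf("seed %d", seed))
    expect_constraints_hold(fit, blk)
    expect_true(all(is.finite(fit$weights$U)), info = sprintf("seed %d", seed))
    expect_lte(fit$n_iter, hyperparams()$max_iter)
  }
})

test_that("strong orthogonality penalties stay stable on unit-scale data", {
  blk <- make_block(n = 40, p = 6, q = 8, seed = 31)
  fit <- fit_mtoscca(blk, hyperparams(lambda_v3 = 5, lambda_u2 = 5))
  tr <- fit$objective_trace
  expect_true(all(is.finite(tr)))
  expect_true(all(diff(tr) <= 1e-6 * (1 + abs(tr[1]))))
  expect_constraints_hold(fit, blk)
})

test_that("near-zero-noise simulation is recovered with high correlation", {
  hp <- hyperparams(0, 0, 0.01, 0, 0.1)
  sim <- simulate_block(sim_config(n = 60, p = 20, q = 40,
                                   noise_sigma = 1e-9, seed = 41))
  for (fit in list(fit_mtoscca(sim$block, hp), fit_mtscca(sim$block, hp))) {
    expect_true(all(abs(fit$ccc) >= 0.95))
  }
})
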