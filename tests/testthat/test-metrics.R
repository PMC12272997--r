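test_that("pearson_cor matches the textbook covariance-ratio formula", {
  a <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(a, 2 * a + 1), 1)
  expect_equal(pearson_cor(a, -a), -1)

  b <- c(1, 3, 2, 4)
  # independent longhand computation
  am <- sum(a) / 4; bm <- sum(b) / 4
  num <- 0; da <- 0; db <- 0
  for (i in 1:4) {
    num <- num + (a[i] - am) * (b[i] - bm)
    da <- da + (a[i] - am)^2
    db <- db + (b[i] - bm)^2
  }
  expect_equal(pearson_cor(a, b), num / sqrt(da * db))
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(1, 2), "n >= 2")
})

test_that("ccc is the correlation of projected scores with the expected symmetries", {
  withr::with_seed(4, {
    X <- matrix(rnorm(200), 20, 10)
    Y <- matrix(rnorm(160), 20, 8)
    u <- rnorm(10)
    v <- rnorm(8)
  })
  expect_equal(ccc(X, u, Y, v), cor(X %*% u, Y %*% v)[1, 1])
  # exact construction: Yv = Xu via least squares on a square system
  Ysq <- matrix(rnorm(100), 10, 10)
  Xsq <- matrix(rnorm(100), 10, 10)
  vfit <- solve(Ysq, Xsq %*% u)
  expect_equal(ccc(Xsq, u, Ysq, vfit), 1)
  # invariance to positive rescaling; sign flip under single negation
  expect_equal(abs(ccc(X, 3 * u, Y, 0.5 * v)), abs(ccc(X, u, Y, v)))
  expect_equal(ccc(X, -u, Y, v), -ccc(X, u, Y, v))
  expect_equal(ccc(X, -u, Y, -v), ccc(X, u, Y, v))
})

test_that("grid enumeration has product cardinality and fixed order", {
  g4 <- grid_spec()
  expect_equal(nrow(grid_combinations(g4)), 1024L)
  g2 <- grid_spec(c(0.1, 1), c(0.1, 1), c(0.1, 1), c(0.1, 1), c(0.1, 1))
  tab <- grid_combinations(g2)
  expect_equal(nrow(tab), 32L)
  # lambda_u2 varies fastest, lambda_v1 slowest
  expect_equal(tab$lambda_u2[1:4], c(0.1, 1, 0.1, 1))
  expect_equal(tab$lambda_v1, rep(c(0.1, 1), each = 16))
  g1 <- grid_spec(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(nrow(grid_combinations(g1)), 1L)
  expect_error(grid_spec(lambda_v1 = numeric(0)), "non-empty")
  expect_error(grid_spec(lambda_v1 = -1), "nonnegative")
})

test_that("grid_search fits every combination and selects the best mean |CCC|", {
  blk <- make_block(n = 30, p = 4, q = 5, seed = 8)
  grid <- grid_spec(c(0.01, 1), 0.01, 0.01, c(0.01, 0.5), 0.01)
  res <- grid_search(blk, grid, solver = "mtoscca", seed = 1)
  expect_equal(nrow(res$table), 4L)
  expect_false(any(res$table$diverged))
  expect_equal(res$table$ccc_mean,
               rowMeans(res$table[, c("ccc1_abs", "ccc2_abs")]))
  expect_equal(res$best, which.max(res$table$ccc_mean))
  # deterministic given seed
  res2 <- grid_search(blk, grid, solver = "mtoscca", seed = 1)
  expect_identical(res$table, res2$table)
})

test_that("train_test_split reproduces the 8:2 arithmetic and partitions", {
  labels138 <- rep(c(1, 0), c(36, 102))  # AD = 1, MCI = 0
  sp <- train_test_split(labels138, 0.2, seed = 3)
  expect_length(sp$train, 110L)
  expect_length(sp$test, 28L)
  expect_setequal(c(sp$train, sp$test), 1:138)

  sp10 <- train_test_split(rep(c(0, 1), 5), 0.2, seed = 1)
  expect_length(sp10$train, 8L)
  expect_length(sp10$test, 2L)

  expect_identical(train_test_split(labels138, 0.2, seed = 7),
                   train_test_split(labels138, 0.2, seed = 7))

  # stratification preserves class counts within rounding
  lab <- rep(c(0, 1), c(80, 20))
  spst <- train_test_split(lab, 0.2, seed = 2, stratified = TRUE)
  expect_equal(sum(lab[spst$test]), 4)
  expect_equal(length(spst$test), 20)

  expect_error(train_test_split(lab, 0), "in \\(0, 1\\)")
  expect_no_error(train_test_split(c(0, 1), 0.5, stratified = TRUE))
})

test_that("kfold_indices partitions with balanced fold sizes", {
  f5 <- kfold_indices(10, 5, seed = 1)
  expect_length(f5, 5L)
  sizes <- vapply(f5, function(f) length(f$validation), 0L)
  expect_true(all(sizes == 2L))
  expect_setequal(unlist(lapply(f5, `[[`, "validation")), 1:10)

  f11 <- kfold_indices(11, 5, seed = 2)
  sizes11 <- sort(vapply(f11, function(f) length(f$validation), 0L),
                  decreasing = TRUE)
  expect_equal(sizes11, c(3L, 2L, 2L, 2L, 2L))
  for (f in f11) {
    expect_setequal(c(f$train, f$validation), 1:11)
    expect_length(intersect(f$train, f$validation), 0L)
  }
  expect_error(kfold_indices(4, 5), "smaller than")
})
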