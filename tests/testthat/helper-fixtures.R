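# In-code fixtures shared across test files. Everything is generated
# programmatically; no data files ship with the tests.

make_fm <- function(n, d, seed = 1, prefix = "f", ids = NULL) {
  vals <- withr::with_seed(seed, matrix(rnorm(n * d), n, d))
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(n))
  feature_matrix(vals, ids, paste0(prefix, seq_len(d)))
}

# Small random two-task block with no planted structure.
make_block <- function(n = 50, p = 8, q = 10, seed = 1, labels = FALSE) {
  X <- make_fm(n, p, seed, prefix = "x")
  Y1 <- make_fm(n, q, seed + 1, prefix = "g")
  Y2 <- make_fm(n, q, seed + 2, prefix = "h")
  lab <- if (labels) withr::with_seed(seed + 3, rbinom(n, 1, 0.4)) else NULL
  assemble_block(X, list(Y1 = Y1, Y2 = Y2), labels = lab)
}

# Write a small delimited matrix file and return its path.
write_fixture_csv <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "m.csv")
  writeLines(lines, path)
  path
}

expect_constraints_hold <- function(fit, block, tol = 1e-8) {
  sb <- standardize(block)
  for (m in seq_len(block$M)) {
    expect_equal(sqrt(sum((sb$X$values %*% fit$weights$U[, m])^2)), 1,
                 tolerance = tol)
    expect_equal(sqrt(sum((sb$Y[[m]]$values %*% fit$weights$V[, m])^2)), 1,
                 tolerance = tol)
  }
}
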