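#' Pearson correlation with explicit degeneracy handling
#'
#' Thin wrapper over the sample Pearson correlation that turns the
#' constant-input case (zero variance, correlation undefined) into a
#' typed validation error instead of an `NA` with a warning.
#'
#' @param a,b numeric vectors of equal length `n >= 2`.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    abort_validation("pearson_cor needs two equal-length vectors, n >= 2")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort_validation("correlation undefined: an input vector is constant")
  }
  stats::cor(a, b)
}

#' Canonical correlation coefficient of one task
#'
#' The per-task performance statistic of the model: the Pearson
#' correlation between the projected scores `X u` and `Y v`. Reported
#' signed; summaries that compare solvers use its absolute value.
#'
#' @param X n x p matrix, `u` length-p weights.
#' @param Y n x q matrix, `v` length-q weights.
#' @param u,v weight vectors.
#' @return Correlation of the two score vectors.
#' @export
ccc <- function(X, u, Y, v) {
  pearson_cor(drop(X %*% u), drop(Y %*% v))
}

#' Hyperparameter search grid
#'
#' Candidate lists for the five penalty strengths. The canonical grid
#' uses \{0.001, 0.01, 0.1, 1\} for each, i.e. `4^5 = 1024`
#' combinations.
#'
#' @param lambda_v1,lambda_v2,lambda_v3,lambda_u1,lambda_u2 nonnegative
#'   candidate vectors.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(lambda_v1 = c(0.001, 0.01, 0.1, 1),
                      lambda_v2 = c(0.001, 0.01, 0.1, 1),
                      lambda_v3 = c(0.001, 0.01, 0.1, 1),
                      lambda_u1 = c(0.001, 0.01, 0.1, 1),
                      lambda_u2 = c(0.001, 0.01, 0.1, 1)) {
  g <- list(lambda_v1 = lambda_v1, lambda_v2 = lambda_v2,
            lambda_v3 = lambda_v3, lambda_u1 = lambda_u1,
            lambda_u2 = lambda_u2)
  for (nm in names(g)) {
    if (!length(g[[nm]]) || !is.numeric(g[[nm]]) || any(g[[nm]] < 0) ||
        any(!is.finite(g[[nm]]))) {
      abort_validation(sprintf(
        "`%s` candidates must be a non-empty vector of nonnegative numbers", nm
      ))
    }
  }
  structure(g, class = "grid_spec")
}

#' Enumerate grid combinations
#'
#' Cartesian product of the candidate lists in fixed lexicographic
#' order: `lambda_v1` varies slowest, `lambda_u2` fastest, so "the k-th
#' combination" is well defined and reproducible.
#'
#' @param grid a [grid_spec()].
#' @return Data frame with one row per combination, columns
#'   `lambda_v1 ... lambda_u2`.
#' @export
grid_combinations <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  g <- expand.grid(
    lambda_u2 = grid$lambda_u2, lambda_u1 = grid$lambda_u1,
    lambda_v3 = grid$lambda_v3, lambda_v2 = grid$lambda_v2,
    lambda_v1 = grid$lambda_v1,
    KEEP.OUT.ATTRS = FALSE
  )
  g[, c("lambda_v1", "lambda_v2", "lambda_v3", "lambda_u1", "lambda_u2")]
}

#' Exhaustive hyperparameter grid search
#'
#' Fits the chosen solver at every combination of [grid_combinations()]
#' and records the absolute per-task canonical correlations and their
#' mean, evaluated in-sample on the full block (matching the canonical
#' selection procedure for this model family). The best row maximizes
#' the mean |CCC|; ties break toward the lowest row index. A fit that
#' errors is recorded with `diverged = TRUE`, excluded from the argmax,
#' and reported with a warning.
#'
#' @param block a [data_block()].
#' @param grid a [grid_spec()].
#' @param solver `"mtoscca"` or `"mtscca"`.
#' @param seed seed forwarded into the solver's hyperparameters.
#' @param hp_base baseline [hyperparams()] supplying the non-penalty
#'   controls (tolerance, iteration cap, ...).
#' @param checkpoint_path optional CSV path; completed rows found there
#'   are reused instead of refit, and each new row is appended as it
#'   finishes, so an interrupted sweep resumes where it stopped.
#' @param progress print a line every `progress` rows (0 = silent).
#' @return A list of class `grid_result`: `table` (one row per
#'   combination: the five lambdas, `ccc*_abs` per task, `ccc_mean`,
#'   `diverged`) and `best` (row index of the winner).
#' @export
grid_search <- function(block, grid = grid_spec(), solver = c("mtoscca", "mtscca"),
                        seed = 1L, hp_base = hyperparams(),
                        checkpoint_path = NULL, progress = 0L) {
  solver <- match.arg(solver)
  combos <- grid_combinations(grid)
  hp_base <- as_hyperparams(hp_base)
  M <- block$M
  fit_fun <- if (solver == "mtoscca") fit_mtoscca else fit_mtscca
  ccc_cols <- paste0("ccc", seq_len(M), "_abs")

  done <- NULL
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    done <- utils::read.csv(checkpoint_path)
  }
  # standardize once so each of the (up to 1024) fits skips it
  if (!is_standardized(block)) block <- standardize(block)

  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    if (!is.null(done) && i <= nrow(done)) {
      rows[[i]] <- done[i, , drop = FALSE]
      next
    }
    hp <- hp_base
    hp[c("lambda_v1", "lambda_v2", "lambda_v3", "lambda_u1", "lambda_u2")] <-
      as.list(combos[i, ])
    hp$seed <- seed
    fit <- tryCatch(fit_fun(block, hp), error = function(e) e)
    row <- combos[i, , drop = FALSE]
    row$row <- i
    if (inherits(fit, "error")) {
      warning(sprintf("grid row %d diverged: %s", i, conditionMessage(fit)))
      for (cc in ccc_cols) row[[cc]] <- NA_real_
      row$ccc_mean <- NA_real_
      row$diverged <- TRUE
    } else {
      ab <- abs(fit$ccc)
      for (m in seq_len(M)) row[[ccc_cols[m]]] <- ab[m]
      row$ccc_mean <- mean(ab)
      row$diverged <- FALSE
    }
    rows[[i]] <- row
    if (!is.null(checkpoint_path)) {
      utils::write.table(
        row, checkpoint_path, sep = ",", row.names = FALSE,
        col.names = !file.exists(checkpoint_path), append = file.exists(checkpoint_path),
        quote = FALSE
      )
    }
    if (progress > 0L && i %% progress == 0L) {
      message(sprintf("grid %d/%d (mean |CCC| so far best %.4f)", i,
                      nrow(combos),
                      suppressWarnings(max(vapply(rows[seq_len(i)], function(r)
                        if (is.na(r$ccc_mean)) -Inf else r$ccc_mean, 0)))))
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  ok <- which(!table$diverged & !is.na(table$ccc_mean))
  if (!length(ok)) abort_numerical("every grid combination diverged")
  best <- ok[which.max(table$ccc_mean[ok])]
  structure(list(table = table, best = best), class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  b <- x$table[x$best, ]
  cat(sprintf(
    "<grid_result> %d combinations; best row %d (mean |CCC| = %.4f)\n",
    nrow(x$table), x$best, b$ccc_mean
  ))
  print(b, row.names = FALSE)
  invisible(x)
}

#' Train/test split of labeled samples
#'
#' Splits `n` labeled samples into disjoint, exhaustive train and test
#' index sets. The test size is `round(n * test_fraction)` (R's
#' round-half-even), train is the remainder — e.g. 138 samples at an
#' 8:2 split give 110 train / 28 test. With `stratified = TRUE`
#' per-class test counts are `round(n_class * test_fraction)`, adjusted
#' by largest fractional remainder so class counts sum to the overall
#' test size.
#'
#' @param labels 0/1 vector of length n.
#' @param test_fraction fraction held out, in (0, 1); default 0.2.
#' @param seed RNG seed driving the permutation.
#' @param stratified split within class (default) or completely at
#'   random.
#' @return List with integer vectors `train` and `test` (1-based).
#' @export
train_test_split <- function(labels, test_fraction = 0.2, seed = 1L,
                             stratified = TRUE) {
  labels <- check_binary_labels(labels)
  n <- length(labels)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    abort_validation("`test_fraction` must be in (0, 1)")
  }
  n_test <- as.integer(round(n * test_fraction))
  if (n_test < 1L || n_test >= n) {
    abort_validation("test fraction leaves an empty train or test set")
  }
  with_seed(seed, {
    if (!stratified) {
      test <- sort(sample.int(n, n_test))
    } else {
      classes <- sort(unique(labels))
      counts <- vapply(classes, function(cl) sum(labels == cl), 0L)
      want <- round(counts * test_fraction)
      rem <- counts * test_fraction - want
      # reconcile rounding so class test counts sum to n_test
      while (sum(want) < n_test) {
        i <- which.max(ifelse(want < counts, rem, -Inf))
        want[i] <- want[i] + 1L
        rem[i] <- -Inf
      }
      while (sum(want) > n_test) {
        i <- which.min(ifelse(want > 0, rem, Inf))
        want[i] <- want[i] - 1L
        rem[i] <- Inf
      }
      if (any(want > counts) || any(want < 0)) {
        abort_validation("a class is too small for the requested test fraction")
      }
      test <- integer(0)
      for (k in seq_along(classes)) {
        idx <- which(labels == classes[k])
        test <- c(test, sample(idx, want[k]))
      }
      test <- sort(test)
    }
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' k-fold cross-validation indices
#'
#' Random balanced partition of `1..n` into `k` validation folds whose
#' sizes differ by at most one.
#'
#' @param n number of samples.
#' @param k number of folds (`2 <= k <= n`).
#' @param seed RNG seed.
#' @return List of `k` lists, each with integer vectors `train` and
#'   `validation`.
#' @export
kfold_indices <- function(n, k = 5L, seed = 1L) {
  check_scalar(n, "n", lower = 2, integerish = TRUE)
  check_scalar(k, "k", lower = 2, integerish = TRUE)
  if (n < k) abort_validation(sprintf("n = %d is smaller than k = %d", n, k))
  perm <- with_seed(seed, sample.int(n))
  # sizes differ by at most 1: first (n mod k) folds get the extra sample
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(f) {
    val <- sort(perm[starts[f]:ends[f]])
    list(train = setdiff(seq_len(n), val), validation = val)
  })
}
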