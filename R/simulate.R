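#' Simulation configuration
#'
#' Parameters of the latent-factor generator used to benchmark the
#' solvers. The defaults mirror the canonical desk-scale design for this
#' model family: `n = 100` samples, an imaging block of `p = 90`
#' region-of-interest features and two genetic blocks of `q = 650`
#' features each, with 10% of loadings nonzero and Gaussian noise whose
#' standard deviation `noise_sigma` is swept over 1..5 in the benchmark.
#'
#' @param n,p,q sample count, imaging width, genetic width.
#' @param noise_sigma noise standard deviation (> 0; floored at 1e-12
#'   internally so "zero noise" requests remain numerically valid).
#' @param sparsity fraction of nonzero true loadings, in (0, 1].
#' @param n_replicates replicate count used by sweep drivers.
#' @param seed RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n = 100L, p = 90L, q = 650L, noise_sigma = 1,
                       sparsity = 0.1, n_replicates = 1L, seed = 1L) {
  check_scalar(n, "n", lower = 2, integerish = TRUE)
  check_scalar(p, "p", lower = 2, integerish = TRUE)
  check_scalar(q, "q", lower = 2, integerish = TRUE)
  check_scalar(noise_sigma, "noise_sigma", lower = 0, strict = TRUE)
  check_scalar(sparsity, "sparsity", lower = 0, strict = TRUE)
  if (sparsity > 1) abort_validation("`sparsity` must be <= 1")
  check_scalar(n_replicates, "n_replicates", lower = 1, integerish = TRUE)
  structure(
    list(n = as.integer(n), p = as.integer(p), q = as.integer(q),
         noise_sigma = max(noise_sigma, 1e-12), sparsity = sparsity,
         n_replicates = as.integer(n_replicates), seed = seed),
    class = "sim_config"
  )
}

# True loadings keep entries at +/-1 (not rescaled to unit norm): the
# per-feature signal standard deviation then equals 1, so the stated
# noise levels 1..5 span per-feature signal-to-noise 1 .. 0.2 — the
# regime in which the benchmark's graded degradation is visible at all.
# Normalizing the loadings would put even the mildest stated noise
# level at 8x the per-feature signal and reduce the sweep to a flat
# noise floor; see the methods vignette.
sparse_loading <- function(d, sparsity) {
  k <- max(1L, round(sparsity * d))
  w <- numeric(d)
  pos <- sample.int(d, k)
  w[pos] <- sample(c(-1, 1), k, replace = TRUE)
  w
}

#' Generate a three-block latent-factor data set
#'
#' Draws one standard-normal latent score vector `c` of length `n` and
#' three sparse loading vectors (`u_true` for the imaging block,
#' `v1_true`, `v2_true` for the two genetic blocks; nonzero positions
#' uniform without replacement, values +/-1), then forms each block as
#' the rank-one signal `c w'` plus independent Gaussian noise of
#' standard deviation `noise_sigma`, drawn freshly per block. Binary
#' labels are derived by thresholding the latent score at zero, so
#' downstream classification evaluation has a planted signal to find.
#'
#' @param config a [sim_config()].
#' @param truth optionally, the `truth` element of a previous call: the
#'   same loading vectors are reused with fresh latent scores and
#'   noise, which is how held-out evaluation data sharing the planted
#'   structure are produced.
#' @return List with `block` (an unstandardized, labeled
#'   [data_block()]) and `truth` (list: `c`, `u_true`, `v1_true`,
#'   `v2_true`, and logical support masks `u_support`, `v1_support`,
#'   `v2_support`).
#' @examples
#' sim <- simulate_block(sim_config(n = 50, p = 10, q = 20, seed = 3))
#' dim(sim$block$X)
#' @export
simulate_block <- function(config = sim_config(), truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    cvec <- stats::rnorm(config$n)
    if (is.null(truth)) {
      u_true <- sparse_loading(config$p, config$sparsity)
      v1_true <- sparse_loading(config$q, config$sparsity)
      v2_true <- sparse_loading(config$q, config$sparsity)
    } else {
      stopifnot(length(truth$u_true) == config$p,
                length(truth$v1_true) == config$q)
      u_true <- truth$u_true
      v1_true <- truth$v1_true
      v2_true <- truth$v2_true
    }
    noise <- function(nr, nc) {
      matrix(stats::rnorm(nr * nc, sd = config$noise_sigma), nr, nc)
    }
    Xv <- tcrossprod(cvec, u_true) + noise(config$n, config$p)
    Y1v <- tcrossprod(cvec, v1_true) + noise(config$n, config$q)
    Y2v <- tcrossprod(cvec, v2_true) + noise(config$n, config$q)
    ids <- sprintf("s%03d", seq_len(config$n))
    X <- feature_matrix(Xv, ids, sprintf("roi%02d", seq_len(config$p)))
    Y1 <- feature_matrix(Y1v, ids, sprintf("snp%03d", seq_len(config$q)))
    Y2 <- feature_matrix(Y2v, ids, sprintf("gene%03d", seq_len(config$q)))
    labels <- as.integer(cvec > 0)
    block <- assemble_block(X, list(Y1 = Y1, Y2 = Y2), labels = labels)
    truth <- list(c = cvec, u_true = u_true, v1_true = v1_true,
                  v2_true = v2_true,
                  u_support = u_true != 0, v1_support = v1_true != 0,
                  v2_support = v2_true != 0)
    list(block = block, truth = truth)
  })
}

#' Noise-robustness sweep of the two solvers
#'
#' For every noise level in `sigmas` and every replicate, generates a
#' fresh latent-factor block and fits each requested solver with shared
#' hyperparameters, recording the absolute canonical correlations.
#' Returns per-(solver, sigma) means and standard deviations — the
#' standard benchmark showing how quickly each solver's recovered
#' correlation degrades as noise drowns the rank-one signal.
#'
#' With `eval = "holdout"` (the default) the canonical correlations are
#' computed on an independently generated block of the same size that
#' shares the planted loading vectors (fresh latent scores and noise).
#' This matters: with more task features than samples (q > n) the
#' in-sample correlation of any fitted weight pair saturates near 1 at
#' every noise level, because the task block can reproduce an arbitrary
#' score vector. `eval = "insample"` records the saturating in-sample
#' values instead.
#'
#' @param config a [sim_config()] providing n, p, q, sparsity.
#' @param sigmas noise standard deviations to sweep (default 1..5).
#' @param solvers character subset of `c("mtoscca", "mtscca")`.
#' @param hp shared [hyperparams()].
#' @param n_replicates replicates per noise level (default from
#'   `config`).
#' @param seed base seed; replicate r at sigma index s uses seeds
#'   derived from `seed + 1000*s + r` so every cell is independently
#'   reproducible.
#' @param eval `"holdout"` (default) or `"insample"`; see Details.
#' @return List of class `noise_sweep`: `summary` (solver, sigma,
#'   per-task mean/sd of |CCC|, `n_ok`) and `raw` (per-replicate rows).
#' @export
noise_sweep <- function(config = sim_config(), sigmas = 1:5,
                        solvers = c("mtoscca", "mtscca"),
                        hp = hyperparams(), n_replicates = config$n_replicates,
                        seed = config$seed, eval = c("holdout", "insample")) {
  solvers <- match.arg(solvers, several.ok = TRUE)
  eval <- match.arg(eval)
  stopifnot(length(sigmas) >= 1L, all(sigmas > 0))
  hp <- as_hyperparams(hp)
  fit_funs <- list(mtoscca = fit_mtoscca, mtscca = fit_mtscca)
  raw <- list()
  for (s in seq_along(sigmas)) {
    for (r in seq_len(n_replicates)) {
      cfg <- config
      cfg$noise_sigma <- sigmas[s]
      cfg$seed <- seed + 1000L * s + r
      sim <- simulate_block(cfg)
      sblock <- standardize(sim$block)
      eval_block <- if (eval == "holdout") {
        cfg2 <- cfg
        cfg2$seed <- cfg$seed + 500000L
        standardize(simulate_block(cfg2, truth = sim$truth)$block)
      } else {
        sblock
      }
      for (sv in solvers) {
        fit <- tryCatch(fit_funs[[sv]](sblock, hp), error = function(e) e)
        if (inherits(fit, "error")) {
          warning(sprintf("fit failed (solver %s, sigma %g, rep %d): %s",
                          sv, sigmas[s], r, conditionMessage(fit)))
          next
        }
        cc <- vapply(seq_len(eval_block$M), function(m) {
          abs(ccc(eval_block$X$values, fit$weights$U[, m],
                  eval_block$Y[[m]]$values, fit$weights$V[, m]))
        }, 0)
        raw[[length(raw) + 1L]] <- data.frame(
          solver = sv, sigma = sigmas[s], replicate = r,
          ccc1_abs = cc[1L],
          ccc2_abs = if (length(cc) > 1L) cc[2L] else NA_real_
        )
      }
    }
  }
  raw <- do.call(rbind, raw)
  agg <- function(f) {
    stats::aggregate(cbind(ccc1_abs, ccc2_abs) ~ solver + sigma, raw, f)
  }
  means <- agg(mean)
  sds <- agg(stats::sd)
  counts <- stats::aggregate(replicate ~ solver + sigma, raw, length)
  summary <- data.frame(
    solver = means$solver, sigma = means$sigma,
    ccc1_mean = means$ccc1_abs, ccc1_sd = sds$ccc1_abs,
    ccc2_mean = means$ccc2_abs, ccc2_sd = sds$ccc2_abs,
    n_ok = counts$replicate
  )
  summary <- summary[order(summary$solver, summary$sigma), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, raw = raw), class = "noise_sweep")
}

#' @export
print.noise_sweep <- function(x, ...) {
  cat("<noise_sweep>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
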