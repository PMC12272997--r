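#' Area under the ROC curve
#'
#' Rank-statistic AUC: the probability that a randomly chosen case
#' (label 1) scores above a randomly chosen control (label 0), with
#' ties counted one half. Scores are used as-is — an AUC below 0.5
#' (a feature whose high values mark controls) is reported as-is, with
#' no automatic direction flipping.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary_labels(labels, length(scores))
  if (anyNA(scores) || any(!is.finite(scores))) {
    abort_validation("scores must be finite and non-missing")
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort_validation("both classes must be present to compute an AUC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: for each case, the fraction of controls it
# beats (ties half); and symmetrically for controls.
delong_placements <- function(scores, labels) {
  cases <- scores[labels == 1L]
  controls <- scores[labels == 0L]
  v10 <- vapply(cases, function(x) {
    mean((x > controls) + 0.5 * (x == controls))
  }, 0)
  v01 <- vapply(controls, function(y) {
    mean((cases > y) + 0.5 * (cases == y))
  }, 0)
  list(v10 = v10, v01 = v01)
}

#' Confidence interval for an AUC
#'
#' 95% (by default) interval for [roc_auc()]. `"delong"` (default) uses
#' the asymptotic placement-value variance estimator — deterministic,
#' the standard choice for reporting per-marker AUCs. `"bootstrap"`
#' resamples cases and controls separately (stratified, so no resample
#' can collapse to a single class) and takes percentile bounds. Both
#' intervals are clipped to `[0, 1]`.
#'
#' @inheritParams roc_auc
#' @param method `"delong"` or `"bootstrap"`.
#' @param conf confidence level, default 0.95.
#' @param n_boot bootstrap replicates (>= 100), default 2000.
#' @param seed RNG seed (bootstrap only).
#' @return Numeric vector `c(lower, upper)`.
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   conf = 0.95, n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  labels <- check_binary_labels(labels, length(scores))
  a <- roc_auc(scores, labels)
  alpha <- (1 - conf) / 2
  if (method == "delong") {
    pl <- delong_placements(scores, labels)
    v <- stats::var(pl$v10) / length(pl$v10) +
      stats::var(pl$v01) / length(pl$v01)
    z <- stats::qnorm(1 - alpha)
    ci <- a + c(-1, 1) * z * sqrt(v)
  } else {
    if (n_boot < 100L) abort_validation("n_boot must be at least 100")
    idx1 <- which(labels == 1L)
    idx0 <- which(labels == 0L)
    aucs <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      i <- c(sample(idx1, length(idx1), replace = TRUE),
             sample(idx0, length(idx0), replace = TRUE))
      roc_auc(scores[i], labels[i])
    }, 0))
    ci <- unname(stats::quantile(aucs, c(alpha, 1 - alpha), type = 7))
  }
  pmin(pmax(ci, 0), 1)
}

rank_by_magnitude <- function(w, names, k) {
  ord <- order(-abs(w), seq_along(w))[seq_len(k)]
  data.frame(feature = names[ord], weight = w[ord],
             abs_weight = abs(w[ord]), row.names = NULL)
}

#' Top-weighted features per block
#'
#' Extracts, for the imaging block and each task block, the `k` features
#' with the largest absolute fitted weight, reported with their signed
#' weight in descending magnitude (ties broken by original feature
#' order). For the imaging weights `U` with several task columns, a
#' feature's magnitude is the Euclidean norm of its weight row (the same
#' grouping the L2,1 penalty acts on) and the reported signed weight is
#' the entry of largest magnitude.
#'
#' @param weights an `scca_fit`, a list with `U`/`V` matrices, or a
#'   plain numeric vector (one block).
#' @param names feature names; only needed for a plain vector without
#'   names.
#' @param k how many features per block (`0 <=` k `<=` feature count).
#' @return For a vector input, one data frame (`feature`, `weight`,
#'   `abs_weight`); otherwise a named list of such tables: `X` for the
#'   imaging block and one per task column of `V`.
#' @export
top_features <- function(weights, names = NULL, k = 10L) {
  check_scalar(k, "k", lower = 0, integerish = TRUE)
  if (is.numeric(weights) && is.null(dim(weights))) {
    nm <- if (!is.null(names)) names else
      if (!is.null(base::names(weights))) base::names(weights) else
        paste0("f", seq_along(weights))
    if (k > length(weights)) {
      abort_validation(sprintf("k = %d exceeds feature count %d", k,
                               length(weights)))
    }
    return(rank_by_magnitude(unname(weights), nm, k))
  }
  task_feature_names <- NULL
  if (inherits(weights, "scca_fit")) {
    task_feature_names <- weights$feature_names$tasks
    weights <- weights$weights
  }
  U <- as.matrix(weights$U)
  V <- as.matrix(weights$V)
  if (k > nrow(U) || k > nrow(V)) {
    abort_validation(sprintf("k = %d exceeds a block's feature count", k))
  }
  u_names <- if (!is.null(rownames(U))) rownames(U) else
    paste0("x", seq_len(nrow(U)))
  v_names_for <- function(m) {
    if (!is.null(task_feature_names)) task_feature_names[[m]]
    else if (!is.null(rownames(V))) rownames(V)
    else paste0("y", seq_len(nrow(V)))
  }
  rown <- sqrt(rowSums(U^2))
  signed <- U[cbind(seq_len(nrow(U)), max.col(abs(U), ties.method = "first"))]
  ordU <- order(-rown, seq_len(nrow(U)))[seq_len(k)]
  out <- list(X = data.frame(feature = u_names[ordU], weight = signed[ordU],
                             abs_weight = rown[ordU], row.names = NULL))
  task_names <- if (!is.null(colnames(V))) colnames(V) else
    paste0("Y", seq_len(ncol(V)))
  for (m in seq_len(ncol(V))) {
    out[[task_names[m]]] <- rank_by_magnitude(V[, m], v_names_for(m), k)
  }
  out
}

block_matrix <- function(block, modality) {
  if (identical(modality, "X")) return(block$X$values)
  if (modality %in% names(block$Y)) return(block$Y[[modality]]$values)
  m <- suppressWarnings(as.integer(modality))
  if (!is.na(m) && m >= 1L && m <= block$M) return(block$Y[[m]]$values)
  abort_validation(sprintf("unknown modality '%s'", modality))
}

extract_features <- function(block, set) {
  cols <- lapply(seq_len(nrow(set)), function(i) {
    mat <- block_matrix(block, set$modality[i])
    if (!set$feature[i] %in% colnames(mat)) {
      abort_validation(sprintf("feature '%s' not found in modality '%s'",
                               set$feature[i], set$modality[i]))
    }
    mat[, set$feature[i]]
  })
  out <- do.call(cbind, cols)
  colnames(out) <- paste(set$modality, set$feature, sep = ":")
  out
}

#' Per-feature ROC report
#'
#' Computes AUC and confidence interval for each feature of a set, using
#' the raw feature values as scores (no direction flipping), typically
#' on a held-out test split.
#'
#' @param block a labeled [data_block()].
#' @param set data frame with columns `modality` (`"X"` or a task name)
#'   and `feature`.
#' @param ci_method,conf,n_boot,seed passed to [auc_ci()].
#' @return Data frame: `predictive_variable`, `modality`, `auc`,
#'   `ci_low`, `ci_high`.
#' @export
per_feature_auc <- function(block, set, ci_method = "delong", conf = 0.95,
                            n_boot = 2000L, seed = 1L) {
  if (is.null(block$labels)) abort_validation("block carries no labels")
  rows <- lapply(seq_len(nrow(set)), function(i) {
    sc <- extract_features(block, set[i, , drop = FALSE])[, 1L]
    ci <- auc_ci(sc, block$labels, method = ci_method, conf = conf,
                 n_boot = n_boot, seed = seed)
    data.frame(predictive_variable = set$feature[i],
               modality = set$modality[i],
               auc = roc_auc(sc, block$labels),
               ci_low = ci[1L], ci_high = ci[2L])
  })
  do.call(rbind, rows)
}

#' Combined-panel AUC on a held-out split
#'
#' For each named feature set, builds a single risk score on the test
#' samples and reports its AUC with confidence interval. A set of one
#' feature is scored by the raw feature itself (so the result is exactly
#' that feature's test AUC); larger sets are combined by a
#' ridge-penalized logistic model (`glmnet`, `alpha = 0`) fitted on the
#' training split only and applied to the test split, keeping all model
#' selection away from the evaluation samples.
#'
#' @param train_block,test_block labeled [data_block()]s over the same
#'   features.
#' @param feature_sets named list; each element a data frame with
#'   columns `modality` and `feature`.
#' @param seed RNG seed (forwarded to bootstrap CIs if requested).
#' @param ci_method,conf,n_boot passed to [auc_ci()].
#' @param ridge_lambda penalty of the logistic combiner (default 0.01).
#' @return Data frame: `predictive_variable` (set name), `auc`,
#'   `ci_low`, `ci_high`, `n_features`.
#' @export
combined_auc <- function(train_block, test_block, feature_sets, seed = 1L,
                         ci_method = "delong", conf = 0.95, n_boot = 2000L,
                         ridge_lambda = 0.01) {
  if (is.null(train_block$labels) || is.null(test_block$labels)) {
    abort_validation("train and test blocks must carry labels")
  }
  if (is.null(names(feature_sets)) || any(!nzchar(names(feature_sets)))) {
    abort_validation("feature_sets must be a named list")
  }
  rows <- lapply(names(feature_sets), function(nm) {
    set <- feature_sets[[nm]]
    if (is.null(set) || !nrow(set)) {
      abort_validation(sprintf("feature set '%s' is empty", nm))
    }
    if (nrow(set) == 1L) {
      sc <- extract_features(test_block, set)[, 1L]
    } else {
      xtr <- extract_features(train_block, set)
      xte <- extract_features(test_block, set)
      fit <- glmnet::glmnet(xtr, factor(train_block$labels, levels = 0:1),
                            family = "binomial", alpha = 0,
                            lambda = ridge_lambda, standardize = TRUE)
      sc <- drop(stats::predict(fit, xte, type = "response"))
    }
    ci <- auc_ci(sc, test_block$labels, method = ci_method, conf = conf,
                 n_boot = n_boot, seed = seed)
    data.frame(predictive_variable = nm, auc = roc_auc(sc, test_block$labels),
               ci_low = ci[1L], ci_high = ci[2L], n_features = nrow(set))
  })
  do.call(rbind, rows)
}

# All non-empty unions of the per-modality top-feature lists, in the
# conventional order: each single modality, each pair, then all three.
panel_combinations <- function(top_sets) {
  nms <- names(top_sets)
  combos <- list()
  for (size in seq_along(nms)) {
    for (pick in utils::combn(nms, size, simplify = FALSE)) {
      label <- paste(paste0("top_", pick), collapse = " + ")
      combos[[label]] <- do.call(rbind, top_sets[pick])
    }
  }
  combos
}

#' End-to-end biomarker evaluation
#'
#' The full evaluation workflow on one labeled multi-block data set:
#' align samples, hold out a stratified test split, optionally shrink
#' over-wide task blocks to the narrowest block's width by
#' random-forest screening on the training samples, fit the chosen
#' solver on the training split, extract the top-`k` features per
#' block, and report per-feature test AUCs plus the combined AUC of
#' every modality-panel union (for three blocks: 7 panels).
#'
#' @param X imaging [feature_matrix()].
#' @param Ys named list of task [feature_matrix()] blocks (possibly of
#'   unequal widths if screening is enabled).
#' @param labels 0/1 vector aligned with `X`'s samples.
#' @param hp [hyperparams()] for the solver.
#' @param solver `"mtoscca"` (default) or `"mtscca"`.
#' @param top_k features reported per block (default 10).
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed RNG seed controlling the split, screening and solver.
#' @param screen `"auto"` (screen any block wider than the narrowest,
#'   the default) or `"none"` (require equal widths).
#' @param ci_method,n_boot passed to [auc_ci()].
#' @return List of class `eval_report`: `per_feature`, `combined`,
#'   `top`, `fit`, `metadata`.
#' @export
evaluate_biomarkers <- function(X, Ys, labels, hp = hyperparams(),
                                solver = c("mtoscca", "mtscca"),
                                top_k = 10L, test_fraction = 0.2, seed = 1L,
                                screen = c("auto", "none"),
                                ci_method = "delong", n_boot = 2000L) {
  solver <- match.arg(solver)
  screen <- match.arg(screen)
  stopifnot(inherits(X, "feature_matrix"))
  if (inherits(Ys, "feature_matrix")) Ys <- list(Y1 = Ys)
  if (is.null(names(Ys)) || any(!nzchar(names(Ys)))) {
    names(Ys) <- paste0("Y", seq_along(Ys))
  }
  labels <- check_binary_labels(labels, nrow(X$values))

  # sample alignment before any splitting
  keep <- X$sample_ids
  for (y in Ys) keep <- keep[keep %in% y$sample_ids]
  if (length(keep) < 10L) {
    abort_validation("fewer than 10 samples shared by all blocks")
  }
  sub_rows <- function(fm, ids) {
    feature_matrix(fm$values[match(ids, fm$sample_ids), , drop = FALSE],
                   ids, fm$feature_names, fm$standardized)
  }
  labels <- labels[match(keep, X$sample_ids)]
  X <- sub_rows(X, keep)
  Ys <- lapply(Ys, sub_rows, ids = keep)

  split <- train_test_split(labels, test_fraction, seed, stratified = TRUE)
  tr <- split$train
  te <- split$test

  widths <- vapply(Ys, function(y) ncol(y$values), 0L)
  q_target <- min(widths)
  screened <- list()
  if (any(widths > q_target)) {
    if (screen == "none") {
      abort_validation(sprintf(
        "task blocks have unequal widths (%s); enable screening",
        paste(widths, collapse = ", ")
      ))
    }
    for (nm in names(Ys)[widths > q_target]) {
      idx <- rf_screen(Ys[[nm]]$values[tr, , drop = FALSE], labels[tr],
                       n_keep = q_target, seed = seed)
      screened[[nm]] <- Ys[[nm]]$feature_names[idx]
      Ys[[nm]] <- feature_matrix(Ys[[nm]]$values[, idx, drop = FALSE],
                                 Ys[[nm]]$sample_ids,
                                 Ys[[nm]]$feature_names[idx])
    }
  }

  sub_block <- function(rows) {
    assemble_block(sub_rows(X, keep[rows]), lapply(Ys, sub_rows, ids = keep[rows]),
                   labels = labels[rows])
  }
  train_block <- sub_block(tr)
  test_block <- sub_block(te)

  hp <- as_hyperparams(hp)
  hp$seed <- seed
  fit_fun <- if (solver == "mtoscca") fit_mtoscca else fit_mtscca
  fit <- fit_fun(train_block, hp)
  top <- top_features(fit, k = top_k)

  task_names <- names(train_block$Y)
  top_sets <- list(X = data.frame(modality = "X", feature = top$X$feature))
  for (nm in task_names) {
    top_sets[[nm]] <- data.frame(modality = nm, feature = top[[nm]]$feature)
  }
  all_set <- do.call(rbind, top_sets)
  per_feature <- per_feature_auc(test_block, all_set, ci_method = ci_method,
                                 n_boot = n_boot, seed = seed)
  combined <- combined_auc(train_block, test_block,
                           panel_combinations(top_sets), seed = seed,
                           ci_method = ci_method, n_boot = n_boot)

  structure(
    list(per_feature = per_feature, combined = combined, top = top, fit = fit,
         metadata = list(seed = seed, solver = solver, ci_method = ci_method,
                         n_train = length(tr), n_test = length(te),
                         top_k = top_k, screened = screened)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> solver %s, %d train / %d test\n",
              x$metadata$solver, x$metadata$n_train, x$metadata$n_test))
  cat("combined panels:\n")
  print(x$combined, row.names = FALSE)
  invisible(x)
}

#' Cross-validated selection stability of the top features
#'
#' Refits the solver on each training fold of a k-fold partition and
#' tabulates how often every feature lands in the per-fold top-`k`
#' lists — the dispersion summary behind a cross-validated ranking.
#'
#' @param block a [data_block()].
#' @param hp [hyperparams()].
#' @param solver `"mtoscca"` or `"mtscca"`.
#' @param k_folds number of folds (default 5).
#' @param top_k list length per fold (default 10).
#' @param seed RNG seed for the fold partition.
#' @return Named list of data frames (`feature`,
#'   `selection_frequency`), one per block, frequency-descending.
#' @export
cv_selection_frequency <- function(block, hp = hyperparams(),
                                   solver = c("mtoscca", "mtscca"),
                                   k_folds = 5L, top_k = 10L, seed = 1L) {
  solver <- match.arg(solver)
  fit_fun <- if (solver == "mtoscca") fit_mtoscca else fit_mtscca
  n <- nrow(block$X$values)
  folds <- kfold_indices(n, k_folds, seed)
  counts <- NULL
  for (f in folds) {
    ids <- block$X$sample_ids[f$train]
    sub <- function(fm) {
      feature_matrix(fm$values[f$train, , drop = FALSE], ids,
                     fm$feature_names)
    }
    tb <- assemble_block(sub(block$X), lapply(block$Y, sub))
    fit <- fit_fun(tb, hp)
    top <- top_features(fit, k = top_k)
    if (is.null(counts)) {
      counts <- lapply(top, function(t) {
        stats::setNames(numeric(0), character(0))
      })
    }
    for (nm in names(top)) {
      for (feat in top[[nm]]$feature) {
        counts[[nm]][feat] <- (if (feat %in% names(counts[[nm]]))
          counts[[nm]][[feat]] else 0) + 1
      }
    }
  }
  lapply(counts, function(ct) {
    df <- data.frame(feature = names(ct),
                     selection_frequency = as.numeric(ct) / k_folds)
    df[order(-df$selection_frequency, df$feature), , drop = FALSE]
  })
}
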