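# Minimal CART random forest for binary labels, used for SNP screening.
# The pinned R environment ships no random-forest package, so this file
# provides the small amount of forest machinery the screening step
# needs: bootstrap bagging, Gini-gain axis splits over an mtry feature
# subsample, out-of-the-box probability averaging, and impurity
# (mean-decrease-Gini) importances. It is written for d up to a few
# thousand features and n up to a few hundred samples — the scale of a
# candidate-SNP screen — not as a general-purpose learner.

gini_impurity <- function(n1, n) {
  p <- n1 / n
  1 - p^2 - (1 - p)^2
}

# Best axis-aligned split of (x[idx, feats], y[idx]) by Gini gain.
best_split <- function(x, y, idx, feats) {
  n <- length(idx)
  yv <- y[idx]
  n1 <- sum(yv)
  parent <- gini_impurity(n1, n)
  if (parent <= 0) return(NULL)
  best <- NULL
  best_gain <- 1e-12
  for (f in feats) {
    xv <- x[idx, f]
    ord <- order(xv, method = "radix")
    xs <- xv[ord]
    cut_ok <- which(xs[-n] < xs[-1L])  # split between distinct values
    if (!length(cut_ok)) next
    cum1 <- cumsum(yv[ord])
    nl <- cut_ok
    nr <- n - nl
    pl <- cum1[cut_ok]
    pr <- n1 - pl
    child <- (nl * gini_impurity(pl, nl) + nr * gini_impurity(pr, nr)) / n
    gains <- parent - child
    j <- which.max(gains)
    if (gains[j] > best_gain) {
      best_gain <- gains[j]
      cut <- cut_ok[j]
      best <- list(feature = f,
                   threshold = (xs[cut] + xs[cut + 1L]) / 2,
                   gain = gains[j], n = n)
    }
  }
  best
}

tree_predict <- function(nodes, x) {
  out <- numeric(nrow(x))
  recurse <- list(list(node = 1L, rows = seq_len(nrow(x))))
  while (length(recurse)) {
    item <- recurse[[length(recurse)]]
    recurse[[length(recurse)]] <- NULL
    nd <- nodes[[item$node]]
    if (nd$leaf) {
      out[item$rows] <- nd$pred
      next
    }
    go_left <- x[item$rows, nd$feature] <= nd$threshold
    if (any(go_left)) {
      recurse[[length(recurse) + 1L]] <- list(node = nd$left,
                                              rows = item$rows[go_left])
    }
    if (any(!go_left)) {
      recurse[[length(recurse) + 1L]] <- list(node = nd$right,
                                              rows = item$rows[!go_left])
    }
  }
  out
}

#' Fit a random forest classifier (binary labels)
#'
#' Bagged CART trees with Gini splits and `mtry` feature subsampling;
#' see the file-level note in the source for scope. Importances are
#' impurity-based: the Gini gain of every split, weighted by the number
#' of samples reaching the node, summed per feature and averaged over
#' trees.
#'
#' @param x numeric matrix (samples x features).
#' @param y 0/1 labels.
#' @param n_trees number of trees (default 200).
#' @param mtry features tried per split (default `floor(sqrt(d))`).
#' @param max_depth maximum tree depth (default 10).
#' @param min_node minimum samples to attempt a split (default 2).
#' @param seed RNG seed; fits are bit-reproducible given it.
#' @return Object of class `mtoscca_rf` with `trees`, `importance`
#'   (named if `x` has column names), and the settings used.
#' @export
random_forest <- function(x, y, n_trees = 200L, mtry = NULL, max_depth = 10L,
                          min_node = 2L, seed = 1L) {
  x <- as.matrix(x)
  y <- check_binary_labels(y, nrow(x))
  if (length(unique(y)) < 2L) {
    abort_validation("both classes must be present to fit a classifier")
  }
  d <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(d)))
  check_scalar(n_trees, "n_trees", lower = 1, integerish = TRUE)
  check_scalar(mtry, "mtry", lower = 1, integerish = TRUE)
  check_scalar(max_depth, "max_depth", lower = 1, integerish = TRUE)
  with_seed(seed, {
    importance <- numeric(d)
    trees <- vector("list", n_trees)
    n <- nrow(x)
    for (t in seq_len(n_trees)) {
      boot <- sample.int(n, n, replace = TRUE)
      tr <- grow_tree(x, y, boot, mtry, max_depth, min_node)
      trees[[t]] <- tr$nodes
      importance <- importance + tr$importance
    }
    importance <- importance / n_trees
    names(importance) <- colnames(x)
    structure(
      list(trees = trees, importance = importance, n_trees = n_trees,
           mtry = mtry, max_depth = max_depth, seed = seed),
      class = "mtoscca_rf"
    )
  })
}

grow_tree <- function(x, y, idx, mtry, max_depth, min_node) {
  importance <- numeric(ncol(x))
  nodes <- list()
  queue <- list(list(idx = idx, depth = 0L, parent = 0L, side = ""))
  while (length(queue)) {
    item <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    id <- length(nodes) + 1L
    if (item$parent > 0L) nodes[[item$parent]][[item$side]] <- id
    ni <- item$idx
    pred <- mean(y[ni])
    split <- NULL
    if (length(ni) >= 2L * min_node && item$depth < max_depth) {
      feats <- sample.int(ncol(x), min(mtry, ncol(x)))
      split <- best_split(x, y, ni, feats)
    }
    if (is.null(split)) {
      nodes[[id]] <- list(leaf = TRUE, pred = pred)
      next
    }
    importance[split$feature] <- importance[split$feature] +
      split$gain * split$n
    go_left <- x[ni, split$feature] <= split$threshold
    nodes[[id]] <- list(leaf = FALSE, feature = split$feature,
                        threshold = split$threshold, left = NA_integer_,
                        right = NA_integer_, pred = pred)
    queue[[length(queue) + 1L]] <- list(idx = ni[go_left],
                                        depth = item$depth + 1L,
                                        parent = id, side = "left")
    queue[[length(queue) + 1L]] <- list(idx = ni[!go_left],
                                        depth = item$depth + 1L,
                                        parent = id, side = "right")
  }
  list(nodes = nodes, importance = importance)
}

#' @export
predict.mtoscca_rf <- function(object, newx, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  probs <- rowMeans(vapply(object$trees, tree_predict, numeric(nrow(newx)),
                           x = newx))
  if (type == "prob") probs else as.integer(probs > 0.5)
}

stratified_kfold <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  folds
}

#' Random-forest feature screening
#'
#' Ranks features by random-forest impurity importance and returns the
#' indices of the `n_keep` most important ones — the step that shrinks a
#' wide candidate-SNP block down to the width of the gene block so the
#' multi-task solver sees equal-width tasks. Forest hyperparameters are
#' chosen by an exhaustive grid (`tune_grid`) with stratified
#' cross-validated accuracy before the final fit; screening is intended
#' to be run on training samples only, to keep test-set information out
#' of the selection.
#'
#' @param features a [feature_matrix()] or numeric matrix.
#' @param labels 0/1 diagnosis vector.
#' @param n_keep how many features to keep (`<=` feature count).
#' @param seed RNG seed (tuning, bagging and tie-free ranking are all
#'   deterministic given it).
#' @param n_trees trees in the final forest (default 200).
#' @param tune_grid data frame of candidate settings with columns
#'   `mtry` and `max_depth`; `NULL` (default) uses a small standard
#'   grid; a 1-row grid skips cross-validation.
#' @param cv_folds folds for tuning (default 3).
#' @return Integer vector of `n_keep` feature indices, importance-
#'   descending (ties broken by original order), with the selected
#'   tuning in attribute `"tuning"` and the full importance vector in
#'   attribute `"importance"`.
#' @export
rf_screen <- function(features, labels, n_keep, seed = 1L, n_trees = 200L,
                      tune_grid = NULL, cv_folds = 3L) {
  x <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  y <- check_binary_labels(labels, nrow(x))
  if (length(unique(y)) < 2L) {
    abort_validation("both classes must be present for screening")
  }
  d <- ncol(x)
  check_scalar(n_keep, "n_keep", lower = 1, integerish = TRUE)
  if (n_keep > d) {
    abort_validation(sprintf("n_keep = %d exceeds feature count %d", n_keep, d))
  }
  if (is.null(tune_grid)) {
    tune_grid <- expand.grid(
      mtry = unique(c(max(1L, floor(sqrt(d))), max(1L, floor(d / 5)))),
      max_depth = c(6L, 12L)
    )
  }
  best_cfg <- tune_grid[1L, , drop = FALSE]
  if (nrow(tune_grid) > 1L) {
    folds <- stratified_kfold(y, cv_folds, seed)
    acc <- numeric(nrow(tune_grid))
    for (g in seq_len(nrow(tune_grid))) {
      correct <- 0L
      for (f in seq_len(cv_folds)) {
        tr <- which(folds != f)
        va <- which(folds == f)
        if (length(unique(y[tr])) < 2L) next
        rf <- random_forest(x[tr, , drop = FALSE], y[tr],
                            n_trees = min(50L, n_trees),
                            mtry = tune_grid$mtry[g],
                            max_depth = tune_grid$max_depth[g],
                            seed = seed + 17L * g + f)
        pred <- predict(rf, x[va, , drop = FALSE], type = "class")
        correct <- correct + sum(pred == y[va])
      }
      acc[g] <- correct / length(y)
    }
    best_cfg <- tune_grid[which.max(acc), , drop = FALSE]
  }
  rf <- random_forest(x, y, n_trees = n_trees, mtry = best_cfg$mtry,
                      max_depth = best_cfg$max_depth, seed = seed)
  ord <- order(-rf$importance, seq_len(d))
  out <- ord[seq_len(n_keep)]
  attr(out, "tuning") <- best_cfg
  attr(out, "importance") <- rf$importance
  out
}
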