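test_that("roc_auc equals the pair-counting oracle, including ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3)), 1)
  expect_equal(roc_auc(rep(2, 8), rep(c(0, 1), 4)), 0.5)

  for (seed in 1:6) {
    withr::with_seed(seed, {
      n <- sample(8:20, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
      scores <- sample(1:5, n, replace = TRUE)  # heavy ties
    })
    expect_identical(roc_auc(scores, labels), oracle_auc(scores, labels))
  }

  withr::with_seed(9, {
    s <- rnorm(20)
    l <- rep(c(0, 1), 10)
  })
  expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1)
  expect_equal(roc_auc(exp(s), l), roc_auc(s, l))  # monotone invariance
  expect_error(roc_auc(s, rep(1, 20)), "both classes")
})

test_that("DeLong interval matches a longhand oracle and bootstrap is seeded", {
  withr::with_seed(2, {
    scores <- rnorm(20)
    labels <- rep(c(1, 0), each = 10)
    scores[labels == 1] <- scores[labels == 1] + 1
  })
  ci <- auc_ci(scores, labels, method = "delong")

  # longhand: placement values, sample variances, normal quantile
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  v10 <- sapply(cases, function(x) mean((x > controls) + 0.5 * (x == controls)))
  v01 <- sapply(controls, function(y) mean((cases > y) + 0.5 * (cases == y)))
  a <- mean(v10)
  s10 <- sum((v10 - a)^2) / (length(v10) - 1)
  s01 <- sum((v01 - a)^2) / (length(v01) - 1)
  se <- sqrt(s10 / 10 + s01 / 10)
  expect_equal(unname(ci), pmin(pmax(a + c(-1, 1) * qnorm(0.975) * se, 0), 1),
               tolerance = 1e-12)

  # perfect separation clips at 1
  ps <- c(rep(0, 6), rep(1, 6))
  ci_perf <- auc_ci(seq_len(12), ps, method = "delong")
  expect_equal(ci_perf[2], 1)
  expect_gte(ci_perf[1], 0.99)

  b1 <- auc_ci(scores, labels, method = "bootstrap", n_boot = 300, seed = 5)
  b2 <- auc_ci(scores, labels, method = "bootstrap", n_boot = 300, seed = 5)
  expect_identical(b1, b2)
  expect_true(b1[1] <= roc_auc(scores, labels) &&
                b1[2] >= roc_auc(scores, labels))
  expect_error(auc_ci(scores, labels, method = "bootstrap", n_boot = 10),
               "at least 100")
})

test_that("top_features ranks by magnitude with stable ties", {
  tf <- top_features(c(0.2, -0.9, 0.5), k = 2)
  expect_equal(tf$feature, c("f2", "f3"))
  expect_equal(tf$weight, c(-0.9, 0.5))

  expect_equal(nrow(top_features(c(a = 1, b = 2), k = 0)), 0L)
  expect_error(top_features(c(1, 2), k = 3), "exceeds")

  # tie broken by original order
  tie <- top_features(c(0.5, -0.5, 0.1), k = 2)
  expect_equal(tie$feature, c("f1", "f2"))

  fit <- fit_mtoscca(make_block(n = 40, p = 6, q = 9, seed = 3))
  tops <- top_features(fit, k = 4)
  expect_named(tops, c("X", "Y1", "Y2"))
  expect_equal(vapply(tops, nrow, 0L), c(X = 4L, Y1 = 4L, Y2 = 4L))
  expect_true(all(diff(tops$Y1$abs_weight) <= 0))
})

test_that("combined_auc scores single features raw and panels by ridge logistic", {
  sim <- simulate_block(sim_config(n = 120, p = 10, q = 15,
                                   noise_sigma = 1, seed = 13))
  blk <- sim$block
  sp <- train_test_split(blk$labels, 0.25, seed = 1)
  sub <- function(rows) {
    ids <- blk$X$sample_ids[rows]
    s <- function(fm) feature_matrix(fm$values[rows, , drop = FALSE], ids,
                                     fm$feature_names)
    assemble_block(s(blk$X), lapply(blk$Y, s), labels = blk$labels[rows])
  }
  trb <- sub(sp$train); teb <- sub(sp$test)

  feat <- blk$X$feature_names[which(sim$truth$u_support)[1]]
  sets <- list(single = data.frame(modality = "X", feature = feat),
               pair = data.frame(modality = c("X", "Y1"),
                                 feature = c(feat, blk$Y[[1]]$feature_names[1])))
  out <- combined_auc(trb, teb, sets, seed = 2)
  expect_equal(nrow(out), 2L)
  raw_auc <- roc_auc(teb$X$values[, feat], teb$labels)
  expect_equal(out$auc[out$predictive_variable == "single"], raw_auc)
  expect_true(all(out$ci_low <= out$auc & out$auc <= out$ci_high))

  expect_error(combined_auc(trb, teb, list(bad = data.frame())), "empty")
  expect_error(combined_auc(trb, teb, list(data.frame(modality = "X",
                                                      feature = feat))),
               "named")
})

test_that("evaluate_biomarkers runs end-to-end with screening and 7 panels", {
  sim <- simulate_block(sim_config(n = 120, p = 12, q = 20,
                                   noise_sigma = 1, seed = 17))
  blk <- sim$block
  # widen Y1 with pure-noise columns so screening has work to do
  wideY1 <- feature_matrix(
    cbind(blk$Y[[1]]$values,
          withr::with_seed(1, matrix(rnorm(120 * 10), 120, 10))),
    blk$Y[[1]]$sample_ids,
    c(blk$Y[[1]]$feature_names, paste0("junk", 1:10))
  )
  rep <- evaluate_biomarkers(blk$X, list(Y1 = wideY1, Y2 = blk$Y[[2]]),
                             blk$labels, hp = hyperparams(max_iter = 30),
                             top_k = 3, seed = 5, n_boot = 200)
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep$per_feature), 9L)      # 3 blocks x top 3
  expect_equal(nrow(rep$combined), 7L)         # all panel unions
  expect_equal(ncol(rep$fit$weights$V), 2L)
  expect_length(rep$metadata$screened$Y1, 20L) # screened to q = 20
  expect_true(all(rep$per_feature$auc >= 0 & rep$per_feature$auc <= 1))
  expect_true(all(rep$combined$ci_low <= rep$combined$auc))

  # deterministic end to end
  rep2 <- evaluate_biomarkers(blk$X, list(Y1 = wideY1, Y2 = blk$Y[[2]]),
                              blk$labels, hp = hyperparams(max_iter = 30),
                              top_k = 3, seed = 5, n_boot = 200)
  expect_identical(rep$combined, rep2$combined)
})

test_that("combining informative modalities does not hurt the panel AUC", {
  sim <- simulate_block(sim_config(n = 160, p = 10, q = 12,
                                   noise_sigma = 1.5, seed = 23))
  blk <- sim$block
  rep <- evaluate_biomarkers(blk$X, blk$Y, blk$labels,
                             hp = hyperparams(max_iter = 30), top_k = 3,
                             seed = 7, n_boot = 200)
  singles <- rep$combined$auc[rep$combined$n_features == 3]
  all3 <- rep$combined$auc[which.max(rep$combined$n_features)]
  expect_gte(all3, max(singles) - 0.1)
})

test_that("cv_selection_frequency tabulates fold-stable rankings", {
  sim <- simulate_block(sim_config(n = 60, p = 8, q = 10,
                                   noise_sigma = 0.5, seed = 29))
  freq <- cv_selection_frequency(sim$block, hp = hyperparams(max_iter = 25),
                                 k_folds = 3, top_k = 3, seed = 1)
  expect_named(freq, c("X", "Y1", "Y2"))
  for (tab in freq) {
    expect_true(all(tab$selection_frequency > 0 &
                      tab$selection_frequency <= 1))
  }
})
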