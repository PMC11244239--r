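# Folds, confusion metrics, ROC/AUC, training contracts.

test_that("folds are subject-level, stratified, disjoint and seeded", {
  labels <- rep(c(1L, 0L), each = 5)
  folds <- make_folds(labels, k = 5, seed = 3)
  expect_identical(length(folds), 5L)
  expect_true(all(vapply(folds, length, 0L) == 2L))
  expect_identical(sort(unlist(folds)), 1:10)
  for (f in folds) expect_identical(sort(labels[f]), c(0L, 1L))
  expect_identical(folds, make_folds(labels, k = 5, seed = 3))
  expect_false(identical(folds, make_folds(labels, k = 5, seed = 4)))
  expect_error(make_folds(rep(1L, 6), k = 2), "both classes")
  expect_error(make_folds(c(1L, rep(0L, 9)), k = 5), "stratification")
})

test_that("metrics reproduce the confusion-count formulas", {
  m <- classification_metrics(45, 5, 5, 45)
  expect_equal(c(m$acc, m$sen, m$spe), c(90, 90, 90))
  expect_equal(classification_metrics(10, 0, 0, 10)$acc, 100)
  expect_true(is.nan(classification_metrics(0, 0, 3, 7)$sen))
  expect_error(classification_metrics(0, 0, 0, 0), "empty")
  set.seed(10)
  for (i in 1:1000) {
    cts <- rpois(4, 20)
    if (sum(cts) == 0) cts[1] <- 1
    m <- classification_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m$acc, 100 * (cts[1] + cts[4]) / sum(cts))
    if (cts[1] + cts[2] > 0)
      expect_equal(m$sen, 100 * cts[1] / (cts[1] + cts[2]))
    if (cts[4] + cts[3] > 0)
      expect_equal(m$spe, 100 * cts[4] / (cts[4] + cts[3]))
    # identity: Acc recombines Sen and Spe weighted by class sizes
    if (cts[1] + cts[2] > 0 && cts[3] + cts[4] > 0)
      expect_equal(m$acc,
                   (m$sen * (cts[1] + cts[2]) + m$spe * (cts[3] + cts[4])) /
                     sum(cts))
  }
})

test_that("AUC equals pairwise concordance and is calibrated on noise", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_error(roc_auc(runif(5), rep(1L, 5)), "both classes")
  set.seed(15)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    sc <- round(runif(n), 2)       # coarse scores force ties
    lb <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(sc, lb)$auc, oracle_auc(sc, lb))
  }
  # random scores: mean AUC near 1/2
  aucs <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    roc_auc(runif(1000), sample(rep(0:1, 500)))$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # ROC endpoints
  r <- roc_auc(runif(20), sample(rep(0:1, 10)))$roc
  expect_equal(r$tpr[1], 0); expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[nrow(r)], 1); expect_equal(r$fpr[nrow(r)], 1)
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(33)
  sc <- runif(200); lb <- sample(rep(0:1, 100))
  want <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                         direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(sc, lb)$auc, want, tolerance = 1e-12)
})

test_that("zero learning rate leaves the weights unchanged", {
  cfg <- model_config(width_mult = 1 / 32, fc_width = 8L, seed = 2)
  m <- build_model(cfg)
  set.seed(1)
  x <- array(runif(32 * 32 * 3 * 8), c(32, 32, 3, 8))
  y <- rep(0:1, 4)
  fit <- train_model(m, x, y, train_config(batch_size = 8,
                                           learning_rate = 0,
                                           max_epochs = 3, patience = 3))
  expect_identical(fit$model$layers, m$layers)
})

test_that("training is reproducible and learns a separable toy set", {
  set.seed(20)
  n <- 40
  x <- array(0, c(32, 32, 3, n))
  y <- rep(0:1, each = n / 2)
  for (i in 1:n)
    x[, , , i] <- (if (y[i] == 1) 0.65 else 0.35) +
      array(rnorm(32 * 32 * 3, 0, 0.05), c(32, 32, 3))
  cfg <- model_config(width_mult = 1 / 32, fc_width = 16L, seed = 4)
  tc <- train_config("adam", batch_size = 20, learning_rate = 1e-3,
                     clip_norm = 5, max_epochs = 6, patience = 6, seed = 9)
  f1 <- train_model(build_model(cfg), x, y, tc)
  f2 <- train_model(build_model(cfg), x, y, tc)
  expect_identical(f1$history, f2$history)
  # loss decreases over training and the toy set is learned
  expect_lt(tail(f1$history$train_loss, 1), f1$history$train_loss[1])
  expect_gt(mean(predict_label(f1$model, x) == y), 0.95)
})
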