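# Splits, metrics, and the training loop.

test_that("stratified split hits per-class rounding targets and is seeded", {
  labels <- rep(c(1, 0), c(60, 40))
  sp <- stratified_split(labels, 0.8, seed = 5)
  expect_equal(sum(labels[sp$train] == 1), 48)   # round(60 * 0.8)
  expect_equal(sum(labels[sp$train] == 0), 32)   # round(40 * 0.8)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  expect_identical(stratified_split(labels, 0.8, seed = 5)$train, sp$train)
  expect_false(identical(stratified_split(labels, 0.8, seed = 6)$train, sp$train))
  expect_error(stratified_split(labels, 1.0), "strictly between")
  expect_error(stratified_split(c(1, 1, 1, 0), 0.5), "at least 2")
})

test_that("stratified k-fold partitions the data with balanced classes", {
  labels <- rep(c(1, 0), 50)
  folds <- kfold_stratified(labels, k = 5, seed = 9)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:100)             # exhaustive
  expect_equal(lengths(tests), rep(20L, 5))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(tests[[i]], tests[[j]]), 0)
  }
  # 50/50 balance: every fold within one sample of 10/10
  for (te in tests) {
    expect_gte(sum(labels[te] == 1), 9)
    expect_lte(sum(labels[te] == 1), 11)
  }
  expect_error(kfold_stratified(c(1, 1, 1, 0, 0, 1), k = 5), "at least k")
})

test_that("binarize uses a strict threshold", {
  expect_equal(binarize(c(0.51, 0.49, 0.5), 0.5), c(1L, 0L, 0L))
  expect_equal(binarize(c(0.001, 0.9), 0), c(1L, 1L))
  expect_error(binarize(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("AUC equals the Mann-Whitney statistic and handles separation/ties", {
  # perfectly separated scores
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # uninformative scorer: all scores identical
  expect_equal(auc_score(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  # random case vs the rank-statistic oracle U / (n1 * n0)
  set.seed(61)
  scores <- round(runif(30), 1)                  # ties on purpose
  labels <- rbinom(30, 1, 0.5)
  r <- rank(scores)                              # average-rank convention
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  U <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  expect_equal(auc_score(scores, labels), U / (n1 * n0), tolerance = 1e-12)
  # independent library cross-check
  expect_equal(auc_score(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(62)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.4)
  a0 <- auc_score(scores, labels)
  expect_equal(auc_score(qlogis(scores * 0.98 + 0.01), labels), a0)
  expect_equal(auc_score(scores^3, labels), a0)
})

test_that("ROC points run from (0,0) to (1,1), monotone in both coordinates", {
  set.seed(63)
  r <- roc_points(runif(25), rbinom(25, 1, 0.5))
  expect_equal(unlist(r[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r[nrow(r), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("evaluate_scores returns accuracy even when AUC is undefined", {
  expect_warning(res <- evaluate_scores(c(0.8, 0.7), c(1, 1)), "single-class")
  expect_equal(res$accuracy, 1)
  expect_true(is.na(res$auc))
})

test_that("accuracy on label-independent scores approaches the prevalence", {
  set.seed(64)
  labels <- rbinom(4000, 1, 0.7)
  scores <- runif(4000)                           # independent of labels
  acc <- evaluate_scores(scores, labels)$accuracy
  # guessing at threshold 0.5 on independent scores gives ~0.5 agreement when
  # prediction is a fair coin; with prevalence 0.7 accuracy ~ 0.5
  expect_lt(abs(acc - 0.5), 0.05)
  # while always predicting the majority class attains the prevalence
  expect_lt(abs(mean(labels == 1) - 0.7), 0.05)
})

test_that("hyperparameters enforce the 1:10 learning-rate ratio and positivity", {
  hp <- hyperparams()
  expect_equal(hp$batch_size, 8L)
  expect_equal(hp$lr_new, 1e-3)
  expect_equal(hp$lr_backbone, 1e-4)
  expect_equal(hp$weight_decay, 5e-4)
  expect_equal(hp$epochs, 20L)
  expect_error(hyperparams(lr_backbone = 1e-3), "1:10")
  expect_error(hyperparams(batch_size = 0), "positive")
})

test_that("training records history, picks the best epoch, and reproduces", {
  data <- make_blur_benchmark(n = 24, side = 64, seed = 71)
  sp <- stratified_split(data$labels, 0.75, seed = 71)
  tr <- ns$dataset_subset(data, sp$train)
  te <- ns$dataset_subset(data, sp$test)
  hp <- hyperparams(epochs = 3L, seed = 71)
  fit <- train_model(build_variant("BL", tiny_config(), seed = 71), tr, te, hp)
  expect_equal(nrow(fit$history), 3L)
  expect_equal(fit$accuracy, max(fit$history$test_accuracy))
  expect_equal(fit$history$test_accuracy[fit$best_epoch], fit$accuracy)
  # same seed, same data -> same loss trajectory within tolerance
  fit2 <- train_model(build_variant("BL", tiny_config(), seed = 71), tr, te, hp)
  expect_equal(fit$history$train_loss, fit2$history$train_loss, tolerance = 1e-4)
})

test_that("checkpoints round-trip through disk with identical predictions", {
  data <- make_blur_benchmark(n = 12, side = 64, seed = 72)
  sp <- stratified_split(data$labels, 0.7, seed = 72)
  fit <- train_model(build_variant("BL+SpatialAtt+MS", tiny_config(), seed = 72),
                     ns$dataset_subset(data, sp$train),
                     ns$dataset_subset(data, sp$test),
                     hyperparams(epochs = 1L, seed = 72))
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$checkpoint, p)
  lk <- load_checkpoint(p)
  expect_equal(lk$checkpoint$variant, "BL+SpatialAtt+MS")
  x <- data$images[, , , 1:2, drop = FALSE]
  expect_equal(predict_quality(lk$model, x), predict_quality(fit$model, x))
  # corrupted schema rejected
  bad <- fit$checkpoint; bad$schema <- "other"
  pb <- withr::local_tempfile(fileext = ".rds")
  saveRDS(bad, pb)
  expect_error(load_checkpoint(pb), "schema")
})
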