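cfgT <- tiny_model_config()

test_that("training returns finite loss histories and is seed-reproducible", {
  prep <- mini_prep()
  tc <- train_config(epochs = 2L, seed = 3)
  fit <- train(cfgT, prep[1:10], NULL, tc)
  expect_length(fit$loss_history, 2L)
  expect_true(all(is.finite(fit$loss_history)))

  fit2 <- train(cfgT, prep[1:10], NULL, tc)
  expect_identical(param_checksum(fit$params), param_checksum(fit2$params))
  expect_identical(evaluate(fit$params, prep[11:20])$scores,
                   evaluate(fit2$params, prep[11:20])$scores)
})

test_that("batched training with early stopping consults validation loss", {
  prep <- mini_prep()
  tc <- train_config(batch_size = 4L, seed = 5, patience = 2L,
                     max_epochs = 6L)
  fit <- train(cfgT, prep[1:16], prep[17:24], tc)
  expect_true(length(fit$val_loss_history) <= 6L)
  expect_true(all(is.finite(fit$val_loss_history)))
})

test_that("AUROC matches the pairwise-concordance oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.1),
                     c("active", "active", "inactive", "inactive")), 1.0)
  set.seed(17)
  for (k in 1:5) {
    n <- 200L
    labels <- sample(c("active", "inactive"), n, replace = TRUE)
    scores <- round(stats::runif(n), 2)   # rounding forces ties
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-9)
  }
  expect_warning(a <- auroc(c(0.2, 0.4), c("active", "active")), "one class")
  expect_true(is.na(a))
})

test_that("evaluation reports accuracy, TPR and precision on known cases", {
  prep_fake <- lapply(c("active", "active", "inactive", "inactive"),
                      function(l) list(label = l))
  ev <- evaluate(NULL, prep_fake, scores = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(ev$accuracy, 100)
  expect_equal(ev$auroc, 1.0)
  expect_equal(ev$tpr, 100)
  expect_equal(ev$precision, 100)

  ev2 <- evaluate(NULL, prep_fake, scores = c(0.9, 0.2, 0.8, 0.1))
  expect_equal(ev2$accuracy, 50)
  expect_equal(ev2$tpr, 50)        # TP 1, FN 1
  expect_equal(ev2$precision, 50)  # TP 1, FP 1
  pts <- roc_points(ev2$scores, ev2$labels)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
})

test_that("repeated runs aggregate as mean and sample SD over 3 seeds", {
  prep <- mini_prep()
  rr <- repeated_runs(cfgT, prep[1:12], prep[13:24],
                      train_config(epochs = 1L, seed = 2), repeats = 3L)
  expect_equal(nrow(rr$runs), 3L)
  expect_equal(rr$summary$metric,
               c("accuracy", "auroc", "tpr", "precision"))
  expect_equal(rr$summary$mean[1], mean(rr$runs$accuracy))
  expect_equal(rr$summary$sd[1], stats::sd(rr$runs$accuracy))
  expect_true(all(rr$summary$sd >= 0 | is.na(rr$summary$sd)))
})

test_that("the ablation suite covers the requested items with repeats", {
  prep <- mini_prep()
  tab <- run_ablation_suite(prep[1:10], prep[11:18], items = c(1L, 6L, 7L),
                            repeats = 2L, model_cfg = cfgT,
                            train_cfg = train_config(epochs = 1L, seed = 1))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$ablated_item, c(1L, 6L, 7L))
  expect_equal(tab$repeats, rep(2L, 3L))
  expect_false("linker" %in% strsplit(tab$branches[2], "+", fixed = TRUE)[[1]])
  expect_equal(strsplit(tab$branches[3], "+", fixed = TRUE)[[1]],
               c("poi_pocket", "warhead", "linker"))
  expect_true(all(is.finite(tab$accuracy_mean)))
})

test_that("leave-one-target-out excludes the held-out POI from training", {
  prep <- mini_prep()
  pois <- vapply(prep, `[[`, character(1), "poi_name")
  target <- names(sort(table(pois), decreasing = TRUE))[1]
  res <- leave_one_target_out(prep, target, cfgT,
                              train_config(epochs = 1L, seed = 9))
  expect_equal(res$held_out$n, sum(pois == target))
  expect_lte(res$residual$n, ceiling(0.2 * sum(pois != target)))
  expect_error(leave_one_target_out(prep, "NOPE", cfgT), "no records")
})

test_that("SVM and RF baselines follow the printed hyperparameters", {
  set.seed(6)
  n <- 200L
  X <- cbind(stats::rnorm(n), stats::rnorm(n))
  X <- X[abs(rowSums(X)) > 0.5, ][1:60, ]   # separable with a margin
  y <- ifelse(X[, 1] + X[, 2] > 0, "active", "inactive")
  colnames(X) <- c("f1", "f2")
  svm_fit <- train_svm(X, y)
  expect_equal(svm_fit$fit$kernel, 0L)      # linear
  expect_equal(svm_fit$fit$cost, 1)
  s <- predict(svm_fit, X)
  expect_true(all(s >= 0 & s <= 1))
  cls <- as.character(stats::predict(svm_fit$fit, X))
  expect_equal(mean(cls == y), 1)           # training accuracy 100%

  rf_fit <- train_rf(X, y, seed = 1)
  expect_equal(rf_fit$fit$num.trees, 100L)
  sr <- predict(rf_fit, X)
  expect_true(all(sr >= 0 & sr <= 1))

  # depth-5 trees cannot memorize a deep parity interaction
  set.seed(8)
  Xp <- matrix(sample(0:1, 200 * 8, replace = TRUE), 200, 8)
  colnames(Xp) <- paste0("b", 1:8)
  yp <- ifelse(rowSums(Xp) %% 2 == 0, "active", "inactive")
  rf_p <- train_rf(Xp, yp, seed = 2)
  acc <- mean((predict(rf_p, Xp) > 0.5) == (yp == "active"))
  expect_lt(acc, 1)
})

test_that("paired comparison of configurations is a two-sided t-test", {
  a <- c(70.1, 71.2, 69.8)
  b <- c(72.3, 73.1, 71.9)
  ht <- compare_configurations(a, b)
  expect_equal(ht$alternative, "two.sided")
  expect_equal(unname(ht$parameter), 2)      # paired: df = n - 1
  expect_equal(unname(ht$estimate), mean(a - b), tolerance = 1e-12)
})
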