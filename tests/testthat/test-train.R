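small_model <- function(n = 1024, seed = 1) {
  build_yamnet_1d(input_samples = n, channels = c(8, 16), strides = c(4, 4),
                  seed = seed)
}

test_that("training is deterministic for a fixed configuration and seed", {
  tr <- synth_set(4, 10, duration_s = 0.128, sr = 8000)
  va <- synth_set(2, 90, duration_s = 0.128, sr = 8000)
  cfg <- train_config(learning_rate = 1e-3, train_batch = 6, epochs = 3, seed = 5)
  f1 <- train(small_model(1024, 3), tr, va, cfg)
  f2 <- train(small_model(1024, 3), tr, va, cfg)
  expect_identical(f1$curves, f2$curves)
  expect_equal(nrow(f1$curves), 3)  # learning-curve length = epochs
})

test_that("a single batch can be overfit", {
  tr <- synth_set(3, 40, duration_s = 0.128, sr = 8000)
  cfg <- train_config(learning_rate = 2e-3, train_batch = 9, epochs = 200,
                      seed = 2)
  fit <- train(small_model(1024, 2), tr, tr, cfg)
  expect_lt(fit$curves$train_loss[200], 0.1 * fit$curves$train_loss[1])
})

test_that("the kept checkpoint is at least as good as the final epoch", {
  tr <- synth_set(4, 10, duration_s = 0.128, sr = 8000)
  va <- synth_set(2, 90, duration_s = 0.128, sr = 8000)
  fit <- train(small_model(1024, 1), tr, va,
               train_config(learning_rate = 1e-3, train_batch = 6,
                            epochs = 4, seed = 1))
  expect_gte(fit$best_val_accuracy,
             fit$curves$val_accuracy[nrow(fit$curves)] - 1e-9)
  expect_equal(fit$best_val_accuracy, max(fit$curves$val_accuracy))
})

test_that("training aborts with diagnostics when the loss goes non-finite", {
  tr <- synth_set(2, 10, duration_s = 0.128, sr = 8000)
  tr$x[1, 5] <- NaN
  expect_error(
    train(small_model(1024, 1), tr, tr,
          train_config(learning_rate = 1e-3, train_batch = 6, epochs = 5,
                       seed = 1)),
    "lr=0.001.*epoch", class = "tembo_training_error")
})

test_that("evaluation reports the full metric suite", {
  perfect <- eval_report(c("a", "b", "c"), c("a", "b", "c"),
                         classes = c("a", "b", "c"))
  expect_true(all(diag(perfect$confusion_matrix) == 1))
  expect_equal(perfect$overall_accuracy, 1)
  expect_true(all(perfect$per_class$f1 == 1))

  part <- eval_report(c("r", "r", "t"), c("r", "t", "t"), classes = c("r", "t"))
  expect_equal(part$overall_accuracy, 2 / 3)
})

test_that("metrics from a fixed confusion matrix match hand arithmetic", {
  cm <- matrix(c(5, 1, 0,
                 0, 6, 2,
                 1, 0, 3), nrow = 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  rep <- eval_report_from_confusion(cm)
  expect_equal(rep$per_class$precision, c(5 / 6, 6 / 7, 3 / 5))
  expect_equal(rep$per_class$recall, c(5 / 6, 6 / 8, 3 / 4))
  expect_equal(rep$per_class$accuracy, rep$per_class$recall)
  expect_equal(rep$overall_accuracy, 14 / 18)
})

test_that("confusion-matrix identities hold on random label vectors", {
  withr::with_seed(99, {
    for (i in 1:20) {
      classes <- letters[1:3]
      n <- sample(5:60, 1)
      truth <- sample(classes, n, replace = TRUE)
      pred <- sample(classes, n, replace = TRUE)
      rep <- eval_report(truth, pred, classes)
      expect_equal(unname(rowSums(rep$confusion_matrix)),
                   unname(as.vector(table(factor(truth, classes)))))
      expect_equal(rep$overall_accuracy,
                   sum(diag(rep$confusion_matrix)) / n)
      f1 <- rep$per_class$f1
      expect_true(all(f1 >= 0 & f1 <= 1, na.rm = TRUE))
    }
  })
})

test_that("evaluate refuses empty test sets and reports per-class recall", {
  fit <- fixture_trained_fit()
  expect_error(evaluate(fit, list(x = matrix(numeric(0), 0, 10), y = character(0))),
               class = "tembo_validation_error")
  test <- synth_set(5, 7000, duration_s = 0.5, sr = 8000)
  rep <- evaluate(fit, test)
  expect_equal(sum(rep$confusion_matrix), 15)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
})
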