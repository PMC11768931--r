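test_that("separable blobs are fit perfectly and order-invariantly", {
  withr::with_seed(1, {
    x <- rbind(matrix(rnorm(40, mean = 0, sd = 0.2), ncol = 2),
               matrix(rnorm(40, mean = 3, sd = 0.2), ncol = 2))
    y <- rep(c("a", "b"), each = 20)
  })
  fit <- fit_svm_spectral(x, y)
  expect_equal(mean(predict(fit, x) == y), 1)
  perm <- sample(nrow(x))
  fit2 <- fit_svm_spectral(x[perm, ], y[perm])
  expect_identical(predict(fit, x), predict(fit2, x))
})

test_that("the RBF kernel solves XOR where a linear kernel cannot", {
  withr::with_seed(2, {
    corners <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
    x <- do.call(rbind, lapply(1:4, function(i) {
      sweep(matrix(rnorm(20, sd = 0.05), ncol = 2), 2, corners[i, ], "+")
    }))
    y <- rep(c("same", "same", "diff", "diff"), each = 10)
  })
  rbf <- fit_svm_spectral(x, y, cost = 100, gamma = 2)
  expect_equal(mean(predict(rbf, x) == y), 1)
  lin <- e1071::svm(x = x, y = factor(y), kernel = "linear", cost = 100,
                    scale = FALSE)
  expect_lt(mean(as.character(predict(lin, x)) == y), 1)
})

test_that("single-class input is rejected", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_svm_spectral(x, rep("a", 10)),
               class = "tembo_validation_error")
})

test_that("feature-image lists are accepted directly", {
  specs <- default_call_specs(0.5, 8000)
  imgs <- c(lapply(1:4, function(i) build_feature_image(generate_call(specs$rumble, i))),
            lapply(5:8, function(i) build_feature_image(generate_call(specs$trumpet, i))))
  y <- rep(c("rumble", "trumpet"), each = 4)
  fit <- fit_svm_spectral(imgs, y)
  expect_equal(mean(predict(fit, imgs) == y), 1)
})
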