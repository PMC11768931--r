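# Forward contracts, analytic parameter counts, initialization statistics,
# FLOP accounting, and quantization bounds for the model zoo.

test_that("all raw-audio builders emit (batch, 3) probabilities summing to 1", {
  n <- 2048
  x <- matrix(rnorm(2 * n, sd = 0.2), nrow = 2)
  models <- list(
    build_elephant_caller_net(input_samples = n, seed = 1),
    build_mobilenet_v2_raw(input_samples = n, grid = c(32, 64), seed = 1),
    build_yamnet_1d(input_samples = n, seed = 1),
    build_rawnet_residual(input_samples = n, seed = 1)
  )
  for (m in models) {
    p <- predict(m, x)
    expect_equal(dim(p), c(2, 3), info = m$name)
    expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("single-channel 3-class MobileNetV2 has the exact printed count", {
  m <- build_mobilenet_v2_raw(n_classes = 3, in_channels = 1)
  expect_identical(count_parameters(m), 2227139)
  m2 <- build_mobilenet_v2_raw(n_classes = 2, in_channels = 1,
                               input_samples = 2048, grid = c(32, 64))
  m3 <- build_mobilenet_v2_raw(n_classes = 3, in_channels = 1,
                               input_samples = 2048, grid = c(32, 64))
  expect_equal(count_parameters(m3) - count_parameters(m2), 1281)
})

test_that("the mismatched reshape grid raises a shape error", {
  expect_error(build_mobilenet_v2_raw(input_samples = 2048, grid = c(10, 10)),
               class = "tembo_shape_error")
})

test_that("default spatial/temporal network lands in the expected size band", {
  m <- build_elephant_caller_net()
  n <- count_parameters(m)
  expect_gte(n, 4.2e6)
  expect_lte(n, 5.2e6)
})

test_that("impossible pooling chains name the failing stage", {
  expect_error(build_elephant_caller_net(input_samples = 64),
               "stage", class = "tembo_shape_error")
})

test_that("Kaiming initialization gives weight variance near 2/fan_in", {
  m <- build_elephant_caller_net(input_samples = 8000, seed = 42)
  conv <- NULL
  for (l in m$layers) {
    if (l$type == "conv" && length(l$W) >= 1e4) conv <- l
  }
  fan_in <- (conv$in_ch / conv$groups) * conv$kh * conv$kw
  expect_gt(length(conv$W), 1e4)
  v <- var(as.vector(conv$W))
  expect_lt(abs(v - 2 / fan_in) / (2 / fan_in), 0.2)
})

test_that("count_parameters matches hand counts for primitive layers", {
  lin <- new_test_model(list(tembo:::layer_linear(10, 3)))
  expect_equal(count_parameters(lin), 33)
  cv <- new_test_model(list(tembo:::layer_conv(1, 8, kw = 9)))
  expect_equal(count_parameters(cv), 80)
  dw <- new_test_model(list(tembo:::layer_conv(16, 16, kw = 5, groups = 16)))
  expect_equal(count_parameters(dw), 16 * 5 + 16)
  bn <- new_test_model(list(tembo:::layer_bn(32)))
  expect_equal(count_parameters(bn), 64)
})

test_that("doubling widths roughly quadruples pointwise conv parameters", {
  pw_params <- function(mult) {
    m <- build_yamnet_1d(input_samples = 4096, width_mult = mult, seed = 1)
    sum(vapply(m$layers, function(l) {
      if (l$type == "conv" && l$groups == 1 && l$kw == 1) length(l$W) + length(l$b)
      else 0
    }, numeric(1)))
  }
  ratio <- pw_params(2) / pw_params(1)
  expect_gte(ratio, 3.5)
  expect_lte(ratio, 4.5)
})

test_that("a residual block with equal channels adds the analytic count", {
  blk <- tembo:::rawnet_block(64, 64, 3, 1)
  n <- sum(vapply(tembo:::flatten_leaves(tembo:::layer_param_tree(blk)),
                  length, numeric(1)))
  expect_equal(n, 2 * (64 * 64 * 3) + 4 * 64)  # two convs (no bias) + two BNs
})

test_that("zeroing a residual block's convolutions leaves the identity map", {
  blk <- tembo:::rawnet_block(8, 8, 3, 1)
  for (i in seq_along(blk$body)) {
    if (blk$body[[i]]$type == "conv") blk$body[[i]]$W[] <- 0
  }
  x <- array(rnorm(8 * 32 * 2), c(8, 1, 32, 2))
  y <- tembo:::nn_forward(list(blk), x, training = FALSE)$y
  expect_equal(y, x, tolerance = 1e-6)
})

test_that("FLOP estimates follow the declared counting conventions", {
  lin <- new_test_model(list(tembo:::layer_linear(10, 3)), input_samples = 10)
  expect_equal(estimate_flops(lin)$flops_per_input, 2 * 10 * 3 + 3)
  # 1-D conv: 2 * L_out * out_ch * in_ch * k + bias adds
  cv <- new_test_model(list(tembo:::layer_conv(2, 4, kw = 5, ph = 0, pw = 0)),
                       input_samples = 100)
  expect_equal(estimate_flops(cv)$flops_per_input,
               2 * 96 * 4 * 2 * 5 + 96 * 4)
  m <- build_yamnet_1d(input_samples = 4096, seed = 1)
  f1 <- estimate_flops(m, batch = 1)
  f32 <- estimate_flops(m, batch = 32)
  expect_equal(f32$flops_per_batch, 32 * f1$flops_per_input)
})

test_that("int8 quantization bounds the serialized size of weight-dominated models", {
  big <- build_elephant_caller_net(input_samples = 8000, seed = 2)
  ratio <- model_serialized_size(quantize_int8(big)) / model_serialized_size(big)
  expect_lte(ratio, 0.35)
})

test_that("int8 quantization bounds per-tensor error and prediction drift", {
  fit <- fixture_trained_fit()
  model <- fit$model
  q <- quantize_int8(model)
  # per-tensor reconstruction error <= half a quantization step
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    ql <- q$layers[[i]]
    if (l$type %in% c("conv", "linear")) {
      step <- max(abs(l$W)) / 127
      expect_lte(max(abs(ql$W - l$W)), step / 2 + 1e-12)
    }
  }
  test <- synth_set(10, 5000, duration_s = 0.5, sr = 8000)
  agree <- mean(predict(model, test$x, type = "class") ==
                  predict(q, test$x, type = "class"))
  expect_gte(agree, 0.9)
})

test_that("network descriptions profile parameters, FLOPs and bytes", {
  m <- build_yamnet_1d(input_samples = 4096, seed = 1)
  d <- network_description(m)
  expect_equal(d$parameter_count, count_parameters(m))
  expect_gt(d$flops_per_input, 0)
  expect_equal(d$serialized_size_bytes,
               4 * (count_parameters(m) +
                      2 * sum(vapply(m$layers, function(l)
                        if (l$type == "bn") l$ch else 0, numeric(1)))))
  g <- glance(m)
  expect_s3_class(g, "tbl_df")
  p <- withr::local_tempfile()
  save_model(m, p)
  expect_equal(file.size(p), d$serialized_size_bytes)
  expect_true(file.exists(paste0(p, ".json")))
})
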