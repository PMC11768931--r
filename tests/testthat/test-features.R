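test_that("MFCC output obeys the frame-count formula", {
  clip <- sine_clip(100, duration_s = 6, sr = 16000)
  mf <- compute_mfcc(clip)
  expect_equal(dim(mf), c(13, 1 + floor((96000 - 2048) / 512)))
  # concatenating a clip with itself doubles the frame count (within one)
  dbl <- audio_clip(c(clip$samples, clip$samples), 16000)
  expect_lte(abs(ncol(compute_mfcc(dbl)) - 2 * ncol(mf)), 5)
})

test_that("silence produces finite, constant MFCC columns", {
  zero <- audio_clip(numeric(32000), 16000)
  mf <- compute_mfcc(zero)
  expect_true(all(is.finite(mf)))
  expect_true(all(abs(mf - mf[, 1]) < 1e-9))
})

test_that("too-short clips are rejected", {
  expect_error(compute_mfcc(audio_clip(numeric(1000), 16000)),
               class = "tembo_validation_error")
  expect_error(compute_chroma_cqt(audio_clip(numeric(1000), 16000)),
               class = "tembo_validation_error")
})

test_that("chroma CQT maps tones to their pitch classes (C = 0)", {
  a4 <- sine_clip(440, duration_s = 2, sr = 16000)
  ch <- compute_chroma_cqt(a4)
  expect_equal(nrow(ch), 12)
  expect_equal(which.max(rowMeans(ch)) - 1, 9)   # A
  c4 <- sine_clip(261.63, duration_s = 2, sr = 16000)
  expect_equal(which.max(rowMeans(compute_chroma_cqt(c4))) - 1, 0)  # C
  # columns normalized to max 1
  expect_equal(unname(apply(ch, 2, max)), rep(1, ncol(ch)))
})

test_that("all-zero clips give uniform chroma columns, never NaN", {
  zero <- audio_clip(numeric(32000), 16000)
  ch <- compute_chroma_cqt(zero)
  expect_true(all(is.finite(ch)))
  expect_true(all(abs(ch - ch[1, 1]) < 1e-12))
})

test_that("feature images stack MFCC over chroma on a shared frame grid", {
  clip <- generate_call(default_call_specs(1, 16000)$trumpet, 2)
  fi <- build_feature_image(clip)
  expect_equal(nrow(fi$stacked), 25)
  expect_equal(ncol(fi$mfcc), ncol(fi$chroma_cqt))
  expect_true(all(is.finite(fi$stacked)))
  fi2 <- build_feature_image(clip)
  expect_identical(fi$stacked, fi2$stacked)   # extraction is deterministic
})

test_that("normalization uses training statistics only", {
  specs <- default_call_specs(0.5, 8000)
  train_imgs <- lapply(1:6, function(i) {
    build_feature_image(generate_call(specs$rumble, i))
  })
  val_imgs <- lapply(7:9, function(i) {
    build_feature_image(generate_call(specs$trumpet, i))
  })
  norm <- fit_feature_normalizer(train_imgs)
  # fitting before or after the validation images exist changes nothing
  expect_identical(norm, fit_feature_normalizer(train_imgs))
  tr_norm <- do.call(cbind, lapply(train_imgs, function(im) {
    normalize_feature_image(im, norm)$stacked
  }))
  expect_lt(max(abs(rowMeans(tr_norm))), 1e-6)
  expect_lt(max(abs(apply(tr_norm, 1, sd) - 1)), 1e-6)
  # validation rows are not re-centred by their own statistics
  va_norm <- do.call(cbind, lapply(val_imgs, function(im) {
    normalize_feature_image(im, norm)$stacked
  }))
  expect_gt(max(abs(rowMeans(va_norm))), 0.05)
})
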