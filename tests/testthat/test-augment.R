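test_that("time_stretch scales duration and preserves pitch", {
  clip <- sine_clip(100, duration_s = 6, sr = 16000)
  expect_length(time_stretch(clip, 1.0)$samples, 96000)
  half <- time_stretch(clip, 2.0)
  expect_equal(length(half$samples), 48000, tolerance = 512)
  st <- time_stretch(clip, 1.2)
  expect_equal(length(st$samples), 80000)
  peak <- fft_peak_hz(st)
  expect_gte(peak, 97)
  expect_lte(peak, 103)
  expect_error(time_stretch(clip, 0), class = "tembo_validation_error")
})

test_that("pitch_shift preserves duration exactly and scales frequency", {
  clip <- sine_clip(100, duration_s = 2, sr = 16000)
  up <- pitch_shift(clip, 12)
  expect_length(up$samples, length(clip$samples))
  expect_equal(fft_peak_hz(up), 200, tolerance = 6)

  same <- pitch_shift(clip, 0)
  expect_identical(same$samples, clip$samples)

  down <- pitch_shift(sine_clip(400, duration_s = 2, sr = 16000), -12)
  expect_equal(fft_peak_hz(down), 200, tolerance = 6)
  expect_error(pitch_shift(clip, 15), class = "tembo_validation_error")
})

test_that("additive noise hits the requested SNR and is seed-deterministic", {
  clip <- sine_clip(100, duration_s = 1, sr = 8000, amp = 0.5)
  expect_identical(add_gaussian_noise(clip, Inf)$samples, clip$samples)
  noisy <- add_gaussian_noise(clip, 20, seed = 3)
  ratio <- mean((noisy$samples - clip$samples)^2) / mean(clip$samples^2)
  expect_equal(10 * log10(1 / ratio), 20, tolerance = 0.5)
  expect_identical(noisy$samples, add_gaussian_noise(clip, 20, seed = 3)$samples)
  expect_false(identical(noisy$samples,
                         add_gaussian_noise(clip, 20, seed = 4)$samples))
  expect_lte(max(abs(noisy$samples)), 1)
})

test_that("balance_classes tops every class up to the target", {
  man <- synth_manifest(counts = c(roar = 4, rumble = 6, trumpet = 5),
                        duration_s = 0.4, sr = 8000)
  man$split <- "train"
  out_dir <- withr::local_tempdir()
  bal <- balance_classes(man, seed = 2, out_dir = out_dir)
  cnt <- table(bal$label)
  expect_true(all(cnt == 10))  # largest class 6 rounded up to 10
  # originals retained untouched
  expect_identical(bal[seq_len(nrow(man)), ], man)
  aug <- bal[-seq_len(nrow(man)), ]
  expect_true(all(grepl("^aug:", aug$provenance)))
  lens <- vapply(aug$path, function(p) length(load_audio(p)$samples), numeric(1))
  expect_true(all(lens == 3200))  # re-standardized to the fixed duration
})

test_that("balance_classes edge cases", {
  man <- synth_manifest(counts = c(roar = 2, rumble = 2, trumpet = 2),
                        duration_s = 0.3, sr = 8000)
  man$split <- "train"
  same <- balance_classes(man, target_per_class = 2)
  expect_identical(same, man)
  expect_error(balance_classes(man, target_per_class = 1),
               class = "tembo_validation_error")
  man2 <- man[c(1, 3, 5), ]  # one clip per class
  out <- balance_classes(man2, target_per_class = 3, seed = 1,
                         out_dir = withr::local_tempdir())
  expect_equal(nrow(out), 9)
  expect_equal(sum(out$provenance != "original"), 6)
})

test_that("expand_fourfold yields exactly five rows per input", {
  man <- synth_manifest(counts = c(roar = 1, rumble = 1, trumpet = 1),
                        duration_s = 0.3, sr = 8000)
  man$split <- "train"
  out <- expand_fourfold(man, seed = 4, out_dir = withr::local_tempdir())
  expect_equal(nrow(out), 15)
  expect_equal(sort(table(out$label)), sort(5 * table(man$label)))
  kinds <- sub("^aug:([a-z_]+):.*$", "\\1",
               out$provenance[out$provenance != "original"])
  expect_equal(sort(unique(kinds)),
               sort(c("time_stretch", "pitch_shift", "combined", "gaussian_noise")))
  empty <- man[0, ]
  expect_equal(nrow(expand_fourfold(empty)), 0)
})

test_that("augmentation refuses test-split clips", {
  man <- synth_manifest(counts = c(roar = 1, rumble = 1, trumpet = 1),
                        duration_s = 0.3, sr = 8000)
  man$split <- c("train", "test", "train")
  expect_error(expand_fourfold(man), "test", class = "tembo_validation_error")
  expect_error(balance_classes(man), "test", class = "tembo_validation_error")
})

test_that("augmented counts are seed-stable but waveforms differ by seed", {
  man <- synth_manifest(counts = c(roar = 1, rumble = 2, trumpet = 1),
                        duration_s = 0.3, sr = 8000)
  man$split <- "train"
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- balance_classes(man, target_per_class = 3, seed = 1, out_dir = d1)
  b2 <- balance_classes(man, target_per_class = 3, seed = 2, out_dir = d2)
  expect_equal(table(b1$label), table(b2$label))
  new1 <- b1$path[b1$provenance != "original"][1]
  new2 <- b2$path[b2$provenance != "original"][1]
  expect_false(identical(load_audio(new1)$samples, load_audio(new2)$samples))
})

test_that("apply_augmentation_plan routes regimes and guards the test split", {
  man <- synth_manifest(counts = c(roar = 2, rumble = 3, trumpet = 2),
                        duration_s = 0.3, sr = 8000)
  man <- stratified_split(man, seed = 1)
  none <- apply_augmentation_plan(man, "none")
  expect_identical(none, man)
  a2 <- apply_augmentation_plan(man, "approach2", seed = 1,
                                out_dir = withr::local_tempdir())
  n_tv <- sum(man$split != "test")
  expect_equal(nrow(a2), 5 * n_tv + sum(man$split == "test"))
  expect_true(all(a2$provenance[a2$split == "test"] == "original"))
})
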