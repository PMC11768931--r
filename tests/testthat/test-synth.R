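test_that("generate_call returns the exact sample count and is deterministic", {
  specs <- default_call_specs(duration_s = 6, sample_rate = 16000)
  clip <- generate_call(specs$rumble, 11)
  expect_equal(length(clip$samples), 96000)
  expect_identical(clip$samples, generate_call(specs$rumble, 11)$samples)
  expect_false(identical(clip$samples, generate_call(specs$rumble, 12)$samples))
})

test_that("waveforms are bounded and finite for every class", {
  specs <- default_call_specs(duration_s = 0.5, sample_rate = 8000)
  for (lbl in names(specs)) {
    for (seed in 1:5) {
      x <- generate_call(specs[[lbl]], seed)$samples
      expect_true(all(is.finite(x)), info = lbl)
      expect_lte(max(abs(x)), 1)
    }
  }
})

test_that("rumble spectral energy peaks inside the harmonic stack", {
  spec <- call_spec("rumble", c(10, 35), 6, 0.1, c(1, 3),
                    duration_s = 6, sample_rate = 16000)
  for (seed in 1:5) {
    clip <- generate_call(spec, seed)
    peak <- fft_peak_hz(clip)
    expect_gte(peak, 10)
    expect_lte(peak, 35 * 6)
  }
})

test_that("invalid call specs name the offending field", {
  expect_error(call_spec("rumble", c(35, 10), 6, 0.1, c(1, 3)),
               "f0_range", class = "tembo_validation_error")
  expect_error(call_spec("rumble", c(10, 35), 6, 1.5, c(1, 3)),
               "noise_fraction", class = "tembo_validation_error")
  expect_error(call_spec("howl", c(10, 35), 6, 0.1, c(1, 3)),
               "label", class = "tembo_validation_error")
  expect_error(call_spec("trumpet", c(300, 7000), 8, 0.1, c(1, 3),
                         sample_rate = 16000),
               "Nyquist", class = "tembo_validation_error")
})

test_that("default specs keep rumble fundamentals below trumpet fundamentals", {
  specs <- default_call_specs()
  expect_lt(mean(specs$rumble$f0_range), mean(specs$trumpet$f0_range))
})

test_that("generate_dataset writes the configured composition", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(per_class_counts = c(roar = 2, rumble = 2, trumpet = 2),
                      specs = default_call_specs(0.5, 8000),
                      seed = 3, output_dir = dir)
  man <- generate_dataset(cfg)
  expect_equal(nrow(man), 6)
  expect_true(all(file.exists(man$path)))
  expect_true(all(man$provenance == "original"))
  # trumpets are spectrally brighter than rumbles
  cent <- vapply(seq_len(nrow(man)), function(i) {
    cl <- load_audio(man$path[i])
    tembo:::spectral_centroid(cl$samples, cl$sample_rate)
  }, numeric(1))
  expect_gt(mean(cent[man$label == "trumpet"]), mean(cent[man$label == "rumble"]))
})

test_that("zero counts yield an empty manifest and no files", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(per_class_counts = c(roar = 0, rumble = 0, trumpet = 0),
                      specs = default_call_specs(0.5, 8000),
                      output_dir = dir)
  man <- generate_dataset(cfg)
  expect_equal(nrow(man), 0)
  expect_length(list.files(dir, pattern = "wav$"), 0)
})

test_that("identical configs reproduce identical datasets", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  mk <- function(dir) generate_dataset(synth_config(
    per_class_counts = c(roar = 2, rumble = 1, trumpet = 1),
    specs = default_call_specs(0.5, 8000), seed = 9, output_dir = dir))
  m1 <- mk(d1)
  m2 <- mk(d2)
  expect_identical(m1$clip_id, m2$clip_id)
  for (i in seq_len(nrow(m1))) {
    expect_identical(load_audio(m1$path[i])$samples,
                     load_audio(m2$path[i])$samples)
  }
})

test_that("nearest-centroid classifier separates the default classes", {
  # spectral centroid + dominant frequency are enough to tell the three
  # classes apart, which is what makes downstream learnability tests
  # meaningful
  specs <- default_call_specs(duration_s = 1, sample_rate = 8000)
  feats <- list()
  labs <- character(0)
  for (lbl in names(specs)) {
    for (seed in 1:30) {
      cl <- generate_call(specs[[lbl]], seed * 31 + match(lbl, names(specs)))
      feats[[length(feats) + 1]] <- c(
        log(tembo:::spectral_centroid(cl$samples, cl$sample_rate)),
        log(fft_peak_hz(cl))
      )
      labs <- c(labs, lbl)
    }
  }
  X <- scale(do.call(rbind, feats))
  centroids <- do.call(rbind, lapply(unique(labs), function(l) {
    colMeans(X[labs == l, , drop = FALSE])
  }))
  pred <- unique(labs)[apply(X, 1, function(r) {
    which.min(colSums((t(centroids) - r)^2))
  })]
  expect_gte(mean(pred == labs), 0.9)
})
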