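# Shared fixtures, generated in code at test time.

# A pure sine clip.
sine_clip <- function(freq, duration_s = 1, sr = 16000, amp = 0.5,
                      label = NULL) {
  t <- (seq_len(round(duration_s * sr)) - 1) / sr
  audio_clip(amp * sin(2 * pi * freq * t), sr, label = label)
}

fft_peak_hz <- function(clip) {
  tembo:::dominant_frequency(clip$samples, clip$sample_rate)
}

# Synthetic waveform datasets at reduced clip length for training tests.
synth_set <- function(n_per_class, seed0, duration_s = 1, sr = 8000) {
  specs <- default_call_specs(duration_s = duration_s, sample_rate = sr)
  xs <- list()
  ys <- character(0)
  i <- 0
  for (lbl in names(specs)) {
    for (k in seq_len(n_per_class)) {
      i <- i + 1
      xs[[i]] <- generate_call(specs[[lbl]], seed0 + i)$samples
      ys <- c(ys, lbl)
    }
  }
  list(x = do.call(rbind, xs), y = ys)
}

# A small on-disk manifest of short synthetic calls.
synth_manifest <- function(counts = c(roar = 4, rumble = 6, trumpet = 5),
                           duration_s = 0.5, sr = 8000, seed = 1,
                           dir = tempfile("synthman_")) {
  cfg <- synth_config(
    per_class_counts = counts,
    specs = default_call_specs(duration_s = duration_s, sample_rate = sr),
    seed = seed, output_dir = dir
  )
  generate_dataset(cfg)
}

# Wrap a bare layer list as a model for profiling checks.
new_test_model <- function(layers, input_samples = 100) {
  tembo:::new_model("test", layers, 3, input_samples, list())
}

# Lazily trained small classifier, shared across test files (computed once).
fixture_env <- new.env(parent = emptyenv())

fixture_trained_fit <- function() {
  if (is.null(fixture_env$fit)) {
    tr <- synth_set(10, 100, duration_s = 0.5, sr = 8000)
    va <- synth_set(4, 900, duration_s = 0.5, sr = 8000)
    model <- build_yamnet_1d(input_samples = 4000,
                             channels = c(16, 32, 64), strides = c(4, 4, 4),
                             seed = 7)
    fixture_env$fit <- train(model, tr, va,
                             train_config(learning_rate = 1e-3,
                                          train_batch = 10, epochs = 6,
                                          seed = 7))
  }
  fixture_env$fit
}
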