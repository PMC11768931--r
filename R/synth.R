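# Synthetic elephant-like call generator. Three acoustically separable
# classes stand in for field recordings: harmonic low-fundamental rumbles,
# broadband noisy roars, and bright high-fundamental trumpets.

#' Acoustic specification for one synthetic call class
#'
#' @param label Class label, one of `"roar"`, `"rumble"`, `"trumpet"`.
#' @param f0_range Fundamental-frequency interval in Hz, `c(low, high)`.
#' @param n_harmonics Number of harmonics in the stack (positive integer).
#' @param noise_fraction Share of total power carried by broadband noise,
#'   in `[0, 1]`.
#' @param am_rate_range Amplitude-modulation rate interval in Hz.
#' @param duration_s Clip duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @return A `call_spec` object.
#' @export
call_spec <- function(label, f0_range, n_harmonics, noise_fraction,
                      am_rate_range, duration_s = 6, sample_rate = 16000) {
  check_field(is.character(label) && label %in% c("roar", "rumble", "trumpet"),
              "label", "must be one of roar, rumble, trumpet")
  check_field(is.numeric(f0_range) && length(f0_range) == 2 &&
                all(f0_range > 0) && f0_range[1] < f0_range[2],
              "f0_range", "must be c(low, high) with 0 < low < high")
  check_field(is_scalar_num(n_harmonics) && n_harmonics >= 1 &&
                n_harmonics == round(n_harmonics),
              "n_harmonics", "must be a positive integer")
  check_field(is_scalar_num(sample_rate) && sample_rate > 0,
              "sample_rate", "must be positive")
  check_field(f0_range[2] * n_harmonics < sample_rate / 2, "f0_range",
              sprintf("highest harmonic (%g Hz) must stay below Nyquist (%g Hz)",
                      f0_range[2] * n_harmonics, sample_rate / 2))
  check_field(is_scalar_num(noise_fraction) && noise_fraction >= 0 &&
                noise_fraction <= 1,
              "noise_fraction", "must lie in [0, 1]")
  check_field(is.numeric(am_rate_range) && length(am_rate_range) == 2 &&
                all(am_rate_range > 0) && am_rate_range[1] <= am_rate_range[2],
              "am_rate_range", "must be c(low, high), both positive")
  check_field(is_scalar_num(duration_s) && duration_s > 0,
              "duration_s", "must be positive")
  structure(
    list(label = label, f0_range = f0_range, n_harmonics = n_harmonics,
         noise_fraction = noise_fraction, am_rate_range = am_rate_range,
         duration_s = duration_s, sample_rate = sample_rate),
    class = "call_spec"
  )
}

#' Default acoustic specifications for the three call classes
#'
#' Rumbles: very low fundamental (10-35 Hz), rich harmonic stack, little
#' noise, slow amplitude modulation. Trumpets: high fundamental (300-800 Hz),
#' bright harmonics, faster modulation. Roars: intermediate fundamental with
#' a dominant broadband-noise component and rough, fast modulation.
#'
#' At sampling rates too low for a class's full harmonic stack, the harmonic
#' count is capped so the highest harmonic stays below Nyquist.
#'
#' @param duration_s Clip duration in seconds (default 6).
#' @param sample_rate Sampling rate in Hz (default 16000).
#' @return Named list of [call_spec()] objects (`roar`, `rumble`, `trumpet`).
#' @export
default_call_specs <- function(duration_s = 6, sample_rate = 16000) {
  cap <- function(n_harm, f0_high) {
    max(1, min(n_harm, floor(0.95 * sample_rate / 2 / f0_high)))
  }
  list(
    roar = call_spec("roar", c(60, 150), cap(3, 150), 0.6, c(8, 15),
                     duration_s, sample_rate),
    rumble = call_spec("rumble", c(10, 35), cap(6, 35), 0.1, c(1, 3),
                       duration_s, sample_rate),
    trumpet = call_spec("trumpet", c(300, 800), cap(8, 800), 0.15, c(4, 8),
                        duration_s, sample_rate)
  )
}

#' Generate one synthetic call
#'
#' Draws a fundamental uniformly from the spec's `f0_range`, builds a
#' harmonic stack with 1/h amplitude roll-off and random phases, mixes in
#' white Gaussian noise at power share `noise_fraction`, applies sinusoidal
#' amplitude modulation at a rate drawn from `am_rate_range` plus a short
#' raised-cosine fade at both ends, and peak-normalizes to 0.9. Bit-identical
#' for a given `(spec, seed)`.
#'
#' @param spec A [call_spec()].
#' @param seed Integer seed controlling all randomness in this clip.
#' @return An [audio_clip()] of exactly `round(duration_s * sample_rate)`
#'   samples with amplitude in `[-1, 1]`.
#' @export
generate_call <- function(spec, seed) {
  if (!inherits(spec, "call_spec")) {
    abort("invalid `spec`: must be a call_spec object",
          class = "tembo_validation_error")
  }
  n <- round(spec$duration_s * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  withr::with_seed(as.integer(seed), {
    f0 <- runif(1, spec$f0_range[1], spec$f0_range[2])
    h <- seq_len(spec$n_harmonics)
    phases <- runif(spec$n_harmonics, 0, 2 * pi)
    harm <- numeric(n)
    for (k in h) {
      harm <- harm + (1 / k) * sin(2 * pi * k * f0 * t + phases[k])
    }
    noise <- rnorm(n)
    am_rate <- runif(1, spec$am_rate_range[1], spec$am_rate_range[2])
    am_phase <- runif(1, 0, 2 * pi)
    nf <- spec$noise_fraction
    unit <- function(x) if (sum(x^2) == 0) x else x / sqrt(mean(x^2))
    x <- sqrt(1 - nf) * unit(harm) + sqrt(nf) * unit(noise)
    env <- 1 - 0.3 + 0.3 * sin(2 * pi * am_rate * t + am_phase)
    fade_n <- min(round(0.05 * spec$sample_rate), floor(n / 4))
    if (fade_n > 0) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(fade_n) / fade_n))
      env[seq_len(fade_n)] <- env[seq_len(fade_n)] * ramp
      env[n - fade_n + seq_len(fade_n)] <- env[n - fade_n + seq_len(fade_n)] * rev(ramp)
    }
    x <- x * env
    x <- 0.9 * x / max(abs(x))
    audio_clip(x, spec$sample_rate, label = spec$label)
  })
}

#' Configuration for a synthetic dataset
#'
#' @param per_class_counts Named integer vector of clips per class; default
#'   is the reference composition of 77 roar, 95 rumble and 63 trumpet.
#' @param specs Named list of [call_spec()]s, one per class.
#' @param seed Master seed; per-clip randomness is derived from it with a
#'   counter-based sub-seed so adding clips never perturbs earlier clips.
#' @param output_dir Directory where WAV files are written.
#' @return A `synth_config` object.
#' @export
synth_config <- function(per_class_counts = c(roar = 77, rumble = 95, trumpet = 63),
                         specs = default_call_specs(),
                         seed = 1L,
                         output_dir = tempfile("tembo_synth_")) {
  check_field(is.numeric(per_class_counts) && all(per_class_counts >= 0) &&
                !is.null(names(per_class_counts)),
              "per_class_counts", "must be a named non-negative vector")
  check_field(all(names(per_class_counts) %in% names(specs)),
              "specs", "every class in per_class_counts needs a call_spec")
  structure(
    list(per_class_counts = per_class_counts, specs = specs,
         seed = as.integer(seed), output_dir = output_dir),
    class = "synth_config"
  )
}

#' Generate a labelled synthetic dataset
#'
#' Writes one 16-bit PCM WAV per clip under `config$output_dir` and returns
#' the dataset manifest. Identical `(config, seed)` produce identical
#' manifests and waveforms.
#'
#' @param config A [synth_config()].
#' @return A tibble manifest with columns `clip_id`, `path`, `label`,
#'   `split` (`NA` until assigned) and `provenance` (`"original"`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$output_dir)) {
    abort(sprintf("cannot create output directory: %s", config$output_dir),
          class = "tembo_io_error")
  }
  labels <- names(config$per_class_counts)
  rows <- purrr::imap(as.list(config$per_class_counts), function(count, lbl) {
    if (count == 0) return(NULL)
    class_offset <- match(lbl, labels) * 1000000
    purrr::map(seq_len(count), function(i) {
      clip <- generate_call(config$specs[[lbl]], sub_seed(config$seed, class_offset + i))
      clip_id <- sprintf("%s_%03d", lbl, i)
      path <- file.path(config$output_dir, paste0(clip_id, ".wav"))
      save_clip(clip, path)
      tibble(clip_id = clip_id, path = path, label = lbl,
             split = NA_character_, provenance = "original")
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Read a dataset manifest CSV
#' @param path Path to a manifest CSV with header
#'   `clip_id,path,label,split,provenance`.
#' @return A tibble manifest.
#' @export
read_manifest <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character"))
}

#' Write a dataset manifest CSV
#' @param manifest A manifest tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
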