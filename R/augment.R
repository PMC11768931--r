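# Augmentation operators (time stretch, pitch shift, additive Gaussian
# noise) and the two dataset-expansion regimes: class balancing
# ("approach 1") and four-fold expansion ("approach 2").

#' Time-stretch a clip without changing its pitch
#'
#' Phase-vocoder time-scale modification: the output lasts approximately
#' `1/rate` times the input while dominant frequencies are preserved.
#'
#' @param clip An [audio_clip()].
#' @param rate Stretch factor (> 0); 2.0 halves the duration.
#' @return The stretched [audio_clip()].
#' @export
time_stretch <- function(clip, rate) {
  check_field(is_scalar_num(rate) && rate > 0, "rate", "must be > 0")
  if (rate == 1) return(clip)
  y <- phase_vocoder(clip$samples, rate)
  audio_clip(pmax(-1, pmin(1, y)), clip$sample_rate,
             label = clip$label, clip_id = clip$clip_id)
}

#' Pitch-shift a clip without changing its duration
#'
#' Resamples by `2^(semitones/12)` (scaling all frequencies) and then
#' time-stretches back, so the output has exactly the input's length.
#'
#' @param clip An [audio_clip()].
#' @param semitones Shift in semitones; `|semitones|` must not exceed `cap`.
#' @param cap Maximum allowed absolute shift (default 12).
#' @return The shifted [audio_clip()].
#' @export
pitch_shift <- function(clip, semitones, cap = 12) {
  check_field(is_scalar_num(semitones) && abs(semitones) <= cap, "semitones",
              sprintf("must satisfy |semitones| <= %g", cap))
  if (semitones == 0) return(clip)
  f <- 2^(semitones / 12)
  n <- length(clip$samples)
  y <- resample_by_factor(clip$samples, f)   # freqs * f, length n / f
  y <- phase_vocoder(y, rate = 1 / f)        # back to ~n samples
  if (length(y) >= n) y <- y[seq_len(n)] else y <- c(y, numeric(n - length(y)))
  audio_clip(pmax(-1, pmin(1, y)), clip$sample_rate,
             label = clip$label, clip_id = clip$clip_id)
}

#' Add white Gaussian noise at a requested SNR
#'
#' The noise is scaled so that the measured signal-to-noise ratio matches
#' `snr_db` exactly (before the final clip to `[-1, 1]`). `snr_db = Inf` is a
#' no-op. Deterministic for a given seed.
#'
#' @param clip An [audio_clip()].
#' @param snr_db Signal-to-noise ratio in dB (finite, or `Inf` for no-op).
#' @param seed Integer seed.
#' @return The noisy [audio_clip()].
#' @export
add_gaussian_noise <- function(clip, snr_db, seed = 1L) {
  check_field(is.numeric(snr_db) && length(snr_db) == 1 && !is.na(snr_db),
              "snr_db", "must be a number (possibly Inf)")
  if (is.infinite(snr_db)) return(clip)
  x <- clip$samples
  ps <- signal_power(x)
  noise <- withr::with_seed(as.integer(seed), rnorm(length(x)))
  pn_target <- ps / 10^(snr_db / 10)
  noise <- noise * sqrt(pn_target / signal_power(noise))
  audio_clip(pmax(-1, pmin(1, x + noise)), clip$sample_rate,
             label = clip$label, clip_id = clip$clip_id)
}

# Default mild-perturbation parameter ranges: preserve class identity of
# low-frequency calls while adding variety.
aug_param_ranges <- list(
  time_stretch = c(0.8, 1.25),   # stretch rate
  pitch_shift  = c(-2, 2),       # semitones
  gaussian_noise = c(15, 30)     # SNR dB
)

# Apply one named augmentation with seed-derived random parameters; returns
# list(clip, provenance).
apply_augmentation <- function(clip, kind, seed) {
  withr::with_seed(as.integer(seed), {
    switch(kind,
      time_stretch = {
        r <- runif(1, aug_param_ranges$time_stretch[1], aug_param_ranges$time_stretch[2])
        list(clip = time_stretch(clip, r),
             provenance = sprintf("aug:time_stretch:%.3f", r))
      },
      pitch_shift = {
        s <- runif(1, aug_param_ranges$pitch_shift[1], aug_param_ranges$pitch_shift[2])
        list(clip = pitch_shift(clip, s),
             provenance = sprintf("aug:pitch_shift:%+.2f", s))
      },
      combined = {
        r <- runif(1, aug_param_ranges$time_stretch[1], aug_param_ranges$time_stretch[2])
        s <- runif(1, aug_param_ranges$pitch_shift[1], aug_param_ranges$pitch_shift[2])
        list(clip = pitch_shift(time_stretch(clip, r), s),
             provenance = sprintf("aug:combined:%.3f:%+.2f", r, s))
      },
      gaussian_noise = {
        snr <- runif(1, aug_param_ranges$gaussian_noise[1], aug_param_ranges$gaussian_noise[2])
        list(clip = add_gaussian_noise(clip, snr, seed = sub_seed(seed, 97L)),
             provenance = sprintf("aug:gaussian_noise:%.1fdB", snr))
      },
      abort(sprintf("unknown augmentation kind: %s", kind),
            class = "tembo_validation_error")
    )
  })
}

assert_no_test_rows <- function(manifest, what) {
  if (any(!is.na(manifest$split) & manifest$split == "test")) {
    abort(sprintf("%s must never receive test-split clips", what),
          class = "tembo_validation_error")
  }
}

# Augment a manifest row: load, augment, re-standardize to the source
# duration, write, return the new manifest row.
augment_row <- function(row, kind, seed, out_dir, suffix) {
  clip <- load_audio(row$path, label = row$label, clip_id = row$clip_id)
  target_s <- clip_duration(clip)
  res <- apply_augmentation(clip, kind, seed)
  out <- standardize_duration(res$clip, target_s, mode = "pad")
  new_id <- paste0(row$clip_id, "_", suffix)
  path <- file.path(out_dir, paste0(new_id, ".wav"))
  save_clip(out, path)
  tibble(clip_id = new_id, path = path, label = row$label,
         split = row$split, provenance = res$provenance)
}

#' Balance training classes by augmentation (approach 1)
#'
#' Pads every class with augmented copies of randomly chosen originals until
#' each class holds exactly `target_per_class` clips. Original rows are
#' retained untouched; each new clip records its provenance. The default
#' target is the largest class count rounded up to the nearest multiple
#' of 10.
#'
#' @param manifest Training-split manifest (must not contain test rows).
#' @param target_per_class Target clips per class; must be at least the
#'   largest existing class count.
#' @param ops Augmentation kinds to draw from (default time stretch and
#'   pitch shift).
#' @param seed Integer seed.
#' @param out_dir Directory for augmented WAVs (default: beside originals).
#' @return The expanded manifest tibble.
#' @export
balance_classes <- function(manifest, target_per_class = NULL,
                            ops = c("time_stretch", "pitch_shift"),
                            seed = 1L, out_dir = NULL) {
  assert_no_test_rows(manifest, "balance_classes()")
  counts <- table(manifest$label)
  if (is.null(target_per_class)) {
    target_per_class <- ceiling(max(counts) / 10) * 10
  }
  check_field(target_per_class >= max(counts), "target_per_class",
              sprintf("must be >= the largest class count (%d)", max(counts)))
  if (is.null(out_dir)) out_dir <- dirname(manifest$path[1])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  new_rows <- purrr::imap(as.list(counts), function(n, lbl) {
    deficit <- target_per_class - n
    if (deficit == 0) return(NULL)
    src <- manifest[manifest$label == lbl, ]
    withr::with_seed(sub_seed(seed, match(lbl, names(counts))), {
      picks <- src[sample(nrow(src), deficit, replace = TRUE), ]
      kinds <- sample(ops, deficit, replace = TRUE)
      seeds <- sample.int(2^30, deficit)
      purrr::map(seq_len(deficit), function(k) {
        augment_row(picks[k, ], kinds[k], seeds[k], out_dir,
                    suffix = sprintf("bal%03d", k))
      })
    })
  })
  dplyr::bind_rows(manifest, dplyr::bind_rows(purrr::flatten(new_rows)))
}

#' Expand a manifest four-fold by augmentation (approach 2)
#'
#' Every source clip yields exactly four augmented variants -- time stretch,
#' pitch shift, the combination of both, and additive Gaussian noise -- so
#' the output holds five rows per input row. Labels are preserved. Intended
#' for the train and validation splits; test rows are refused.
#'
#' @param manifest Manifest to expand (no test rows).
#' @param seed Integer seed.
#' @param out_dir Directory for augmented WAVs (default: beside originals).
#' @return The expanded manifest tibble (5x the input rows).
#' @export
expand_fourfold <- function(manifest, seed = 1L, out_dir = NULL) {
  assert_no_test_rows(manifest, "expand_fourfold()")
  if (nrow(manifest) == 0) return(manifest)
  if (is.null(out_dir)) out_dir <- dirname(manifest$path[1])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kinds <- c("time_stretch", "pitch_shift", "combined", "gaussian_noise")
  new_rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    purrr::map(seq_along(kinds), function(k) {
      augment_row(manifest[i, ], kinds[k], sub_seed(seed, i * 7L + k),
                  out_dir, suffix = paste0("x4_", kinds[k]))
    })
  })
  dplyr::bind_rows(manifest, dplyr::bind_rows(purrr::flatten(new_rows)))
}

#' Apply an augmentation regime to a split manifest
#'
#' `"approach1"` balances the training split; `"approach2"` expands train and
#' validation five-fold; `"none"` returns the manifest unchanged. The test
#' split is never augmented.
#'
#' @param manifest Split manifest (filled `split` column).
#' @param regime One of `"none"`, `"approach1"`, `"approach2"`.
#' @param seed Integer seed.
#' @param target_per_class Optional approach-1 target.
#' @param out_dir Directory for augmented WAVs.
#' @return The augmented manifest tibble.
#' @export
apply_augmentation_plan <- function(manifest,
                                    regime = c("none", "approach1", "approach2"),
                                    seed = 1L, target_per_class = NULL,
                                    out_dir = NULL) {
  regime <- match.arg(regime)
  if (regime == "none") return(manifest)
  if (regime == "approach1") {
    train <- manifest[manifest$split == "train", ]
    rest <- manifest[manifest$split != "train", ]
    out <- balance_classes(train, target_per_class = target_per_class,
                           seed = seed, out_dir = out_dir)
    return(dplyr::bind_rows(out, rest))
  }
  tv <- manifest[manifest$split %in% c("train", "validation"), ]
  rest <- manifest[!(manifest$split %in% c("train", "validation")), ]
  dplyr::bind_rows(expand_fourfold(tv, seed = seed, out_dir = out_dir), rest)
}
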