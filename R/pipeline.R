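# Preprocessing: fixed-duration standardization, silence trimming, and the
# stratified 80:10:10 split.

#' Standardize a clip to a fixed duration
#'
#' Clips longer than the target keep their leading segment in every mode.
#' Shorter clips are lengthened according to `mode`: `"pad"` (and
#' `"truncate"`) append zeros, `"repeat"` tiles the waveform and truncates to
#' the target. Idempotent: applying it twice equals applying it once.
#'
#' @param clip An [audio_clip()].
#' @param target_s Target duration in seconds (> 0).
#' @param mode One of `"pad"`, `"truncate"`, `"repeat"`.
#' @return An [audio_clip()] of exactly `round(target_s * sample_rate)`
#'   samples.
#' @export
standardize_duration <- function(clip, target_s, mode = c("pad", "truncate", "repeat")) {
  mode <- match.arg(mode)
  check_field(is_scalar_num(target_s) && target_s > 0, "target_s",
              "must be a positive number of seconds")
  n_target <- round(target_s * clip$sample_rate)
  x <- clip$samples
  n <- length(x)
  out <- if (n >= n_target) {
    x[seq_len(n_target)]
  } else if (mode == "repeat") {
    rep_len(x, n_target)
  } else {
    c(x, numeric(n_target - n))
  }
  audio_clip(out, clip$sample_rate, label = clip$label, clip_id = clip$clip_id)
}

#' Trim leading and trailing silence
#'
#' Frames the waveform (25 ms windows, 10 ms hop by default), computes frame
#' RMS, and removes leading/trailing frames whose RMS falls below
#' `threshold_db` relative to the loudest frame. Never returns an empty clip:
#' if every frame is below threshold the clip is returned unchanged.
#'
#' @param clip An [audio_clip()].
#' @param threshold_db Threshold in dB relative to peak frame RMS (negative).
#' @param frame_s,hop_s Frame and hop sizes in seconds.
#' @return The trimmed [audio_clip()].
#' @export
trim_silence <- function(clip, threshold_db = -40, frame_s = 0.025, hop_s = 0.010) {
  check_field(is_scalar_num(threshold_db) && threshold_db < 0, "threshold_db",
              "must be negative dB relative to peak")
  x <- clip$samples
  frame <- max(1L, round(frame_s * clip$sample_rate))
  hop <- max(1L, round(hop_s * clip$sample_rate))
  if (length(x) <= frame) return(clip)
  starts <- seq(1L, length(x) - frame + 1L, by = hop)
  rms <- vapply(starts, function(s) sqrt(mean(x[s:(s + frame - 1L)]^2)), numeric(1))
  peak <- max(rms)
  if (peak == 0) return(clip)
  keep <- rms >= peak * 10^(threshold_db / 20)
  if (!any(keep)) return(clip)
  i1 <- starts[which(keep)[1]]
  last <- tail(which(keep), 1)
  # if the final frame is kept, retain the tail beyond the last full frame
  i2 <- if (last == length(starts)) length(x) else
    min(length(x), starts[last] + frame - 1L)
  audio_clip(x[i1:i2], clip$sample_rate, label = clip$label, clip_id = clip$clip_id)
}

# Per-class split counts for one class of size n under (train, val, test)
# ratios: train = floor(r_train * n); the remainder is divided between
# validation and test proportionally, validation taking the larger half
# (ceil). For 80:10:10 this reproduces 77 -> (61, 8, 8), 95 -> (76, 10, 9),
# 63 -> (50, 7, 6).
split_counts_for_n <- function(n, ratios) {
  n_train <- floor(ratios[1] * n)
  rem <- n - n_train
  w <- ratios[2] / (ratios[2] + ratios[3])
  n_val <- ceiling(rem * w)
  n_test <- rem - n_val
  c(train = n_train, validation = n_val, test = n_test)
}

#' Stratified train/validation/test split
#'
#' Applies the per-class rounding rule (train takes the floor of its share;
#' validation takes the larger half of the remainder) within each class, then
#' assigns members at random under `seed`. Counts are deterministic;
#' membership is seed-randomized.
#'
#' @param manifest A manifest tibble with `clip_id` and `label` columns;
#'   every clip must be labelled.
#' @param ratios Numeric `(train, val, test)` ratios, positive, summing to 1.
#' @param seed Integer seed for membership randomization.
#' @return The manifest with its `split` column filled in
#'   (`"train"`, `"validation"`, `"test"`). The per-class count table is
#'   attached as attribute `"split_counts"` and also available via
#'   [split_counts()].
#' @export
stratified_split <- function(manifest, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  check_field(is.numeric(ratios) && length(ratios) == 3 && all(ratios > 0) &&
                abs(sum(ratios) - 1) < 1e-8,
              "ratios", "must be three positive numbers summing to 1")
  bad <- manifest$clip_id[is.na(manifest$label) | manifest$label == ""]
  if (length(bad) > 0) {
    abort(paste0("unlabelled clips in manifest: ", paste(bad, collapse = ", ")),
          class = "tembo_validation_error")
  }
  out <- withr::with_seed(as.integer(seed), {
    manifest |>
      dplyr::group_by(.data$label) |>
      dplyr::group_modify(function(df, key) {
        cnt <- split_counts_for_n(nrow(df), ratios)
        tags <- rep(c("train", "validation", "test"), times = cnt)
        df$split <- sample(tags)
        df
      }) |>
      dplyr::ungroup()
  })
  out <- out[match(manifest$clip_id, out$clip_id), ]
  counts <- out |>
    dplyr::count(.data$label, .data$split) |>
    tidyr::pivot_wider(names_from = "split", values_from = "n", values_fill = 0L)
  attr(out, "split_counts") <- counts
  out
}

#' Per-class split counts of a split manifest
#' @param manifest A manifest with a filled `split` column.
#' @return Tibble with one row per class and columns `label`, `train`,
#'   `validation`, `test`.
#' @export
split_counts <- function(manifest) {
  manifest |>
    dplyr::count(.data$label, .data$split) |>
    tidyr::pivot_wider(names_from = "split", values_from = "n", values_fill = 0L)
}

#' Run the standard preprocessing over a manifest
#'
#' Loads each clip, trims silence, standardizes to the target duration, and
#' writes the result to `out_dir` (or overwrites in place when `out_dir` is
#' `NULL`).
#'
#' @param manifest Manifest tibble with `path` column.
#' @param target_s Target duration in seconds.
#' @param mode Lengthening mode passed to [standardize_duration()].
#' @param threshold_db Silence threshold passed to [trim_silence()].
#' @param target_sr Pipeline sampling rate; files are resampled on load.
#' @param out_dir Output directory for processed WAVs.
#' @return The manifest with `path` pointing at the processed files.
#' @export
prepare_clips <- function(manifest, target_s = 6, mode = "pad",
                          threshold_db = -40, target_sr = 16000,
                          out_dir = NULL) {
  if (is.null(out_dir)) out_dir <- dirname(manifest$path[1])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  new_paths <- purrr::map_chr(seq_len(nrow(manifest)), function(i) {
    clip <- load_audio(manifest$path[i], target_sr = target_sr,
                       label = manifest$label[i], clip_id = manifest$clip_id[i])
    clip <- trim_silence(clip, threshold_db = threshold_db)
    clip <- standardize_duration(clip, target_s, mode = mode)
    p <- file.path(out_dir, paste0(manifest$clip_id[i], ".wav"))
    save_clip(clip, p)
    p
  })
  manifest$path <- new_paths
  manifest
}
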