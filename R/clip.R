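#' Construct an audio clip
#'
#' The atom of every pipeline stage: a mono waveform with its sample rate and
#' an optional class label.
#'
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @param label Optional class label (character scalar).
#' @param clip_id Optional identifier.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, label = NULL, clip_id = NULL) {
  check_field(is.numeric(samples) && length(samples) > 0, "samples",
              "must be a non-empty numeric vector")
  check_field(is_scalar_num(sample_rate) && sample_rate > 0, "sample_rate",
              "must be a positive number")
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         label = label, clip_id = clip_id),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate
  cat(sprintf("<audio_clip> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$sample_rate, dur,
              if (!is.null(x$label)) paste0(" label=", x$label) else ""))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip An `audio_clip`.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate
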