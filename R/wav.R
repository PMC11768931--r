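# Minimal RIFF/WAVE PCM reader and writer (16- and 24-bit integer formats).
# Only the canonical chunks are handled; anything else is skipped.

#' Write a waveform to a PCM WAV file
#'
#' @param samples Numeric vector (or channels-in-columns matrix) in `[-1, 1]`;
#'   values outside the range are clipped.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file path.
#' @param bits Bits per sample, 16 (default) or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16) {
  check_field(bits %in% c(16L, 24L), "bits", "must be 16 or 24")
  x <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  n_ch <- ncol(x)
  n <- nrow(x)
  full <- 2^(bits - 1)
  q <- pmax(-full, pmin(full - 1, round(pmax(-1, pmin(1, t(x))) * (full - 1))))
  q <- as.vector(q)  # interleaved channels
  block_align <- n_ch * bits / 8L
  data_bytes <- n * block_align
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(q), con, size = 2, endian = "little")
  } else {
    v <- as.integer(q)
    v <- ifelse(v < 0, v + 16777216L, v)  # two's complement, 3 bytes LE
    b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
    writeBin(as.raw(as.vector(b)), con)
  }
  invisible(path)
}

#' Read a PCM WAV file
#'
#' @param path Path to a 16- or 24-bit PCM WAV file.
#' @return A list with `samples` (channels-in-columns matrix scaled to
#'   `[-1, 1]`), `sample_rate`, `bits`, and `n_channels`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("audio file not found: %s", path), class = "tembo_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(sprintf("not a RIFF/WAVE file: %s", path), class = "tembo_format_error")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, integer(), size = 2, endian = "little"),
        n_channels   = readBin(con, integer(), size = 2, endian = "little"),
        sample_rate  = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate    = readBin(con, integer(), size = 4, endian = "little"),
        block_align  = readBin(con, integer(), size = 2, endian = "little"),
        bits         = readBin(con, integer(), size = 2, endian = "little")
      )
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), n = sz)
      break
    } else {
      readBin(con, raw(), n = sz + (sz %% 2L))
    }
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("missing fmt/data chunk in %s", path), class = "tembo_format_error")
  }
  if (fmt$audio_format != 1L || !(fmt$bits %in% c(16L, 24L))) {
    abort(sprintf("unsupported WAV encoding in %s (format %d, %d-bit); only PCM 16/24-bit is supported",
                  path, fmt$audio_format, fmt$bits), class = "tembo_format_error")
  }
  if (fmt$bits == 16) {
    v <- readBin(data_raw, integer(), n = length(data_raw) / 2, size = 2,
                 signed = TRUE, endian = "little")
    x <- v / 32767
  } else {
    b <- as.integer(data_raw)
    n3 <- length(b) %/% 3
    b <- matrix(b[seq_len(n3 * 3)], nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388607
  }
  m <- matrix(x, ncol = fmt$n_channels, byrow = TRUE)
  list(samples = m, sample_rate = fmt$sample_rate, bits = fmt$bits,
       n_channels = fmt$n_channels)
}

#' Load an audio file as a mono clip
#'
#' Reads a PCM WAV file, averages channels to mono, and optionally resamples
#' to the pipeline rate.
#'
#' @param path Path to the WAV file.
#' @param target_sr Optional target sampling rate in Hz; when given and
#'   different from the file's rate, the waveform is resampled (polyphase,
#'   via the signal package) and padded/trimmed to exactly
#'   `round(n * target_sr / native_sr)` samples.
#' @param label,clip_id Optional label and identifier attached to the clip.
#' @return An [audio_clip()].
#' @export
load_audio <- function(path, target_sr = NULL, label = NULL, clip_id = NULL) {
  w <- read_wav(path)
  x <- rowMeans(w$samples)
  sr <- w$sample_rate
  if (!is.null(target_sr) && target_sr != sr) {
    g <- gcd(as.integer(target_sr), as.integer(sr))
    p <- as.integer(target_sr) %/% g
    q <- as.integer(sr) %/% g
    y <- signal::resample(x, p, q)
    n_out <- round(length(x) * target_sr / sr)
    if (length(y) >= n_out) y <- y[seq_len(n_out)] else y <- c(y, numeric(n_out - length(y)))
    x <- pmax(-1, pmin(1, y))
    sr <- target_sr
  }
  audio_clip(x, sr, label = label, clip_id = clip_id %||% basename(path))
}

gcd <- function(a, b) if (b == 0L) a else gcd(b, a %% b)

#' Write an audio clip to disk
#'
#' @param clip An [audio_clip()].
#' @param path Output WAV path.
#' @param bits Bits per sample (16 or 24).
#' @return `path`, invisibly.
#' @export
save_clip <- function(clip, path, bits = 16) {
  write_wav(clip$samples, clip$sample_rate, path, bits = bits)
}
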