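# Spectrogram-pipeline features: MFCC and chroma constant-Q transform,
# stacked into fixed-shape feature images. Frame convention throughout:
# frames start at 1, 1 + hop, ...; frame count = 1 + floor((L - frame)/hop).

# Mel scale (HTK convention).
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank: n_mels x (n_fft/2 + 1).
mel_filterbank <- function(sr, n_fft, n_mels, fmin = 0, fmax = sr / 2) {
  n_bins <- n_fft %/% 2 + 1
  freqs <- (seq_len(n_bins) - 1) * sr / n_fft
  pts <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; mid <- pts[m + 1]; hi <- pts[m + 2]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in).
dct_matrix <- function(n_out, n_in) {
  m <- outer(seq_len(n_out) - 1, seq_len(n_in) - 0.5,
             function(k, n) cos(pi * k * n / n_in))
  m * sqrt(2 / n_in) * ifelse(seq_len(n_out) == 1, sqrt(0.5), 1)
}

#' Mel-frequency cepstral coefficients
#'
#' Hann-windowed power spectrogram, `n_mels`-band triangular mel filterbank,
#' log (floored at `log_floor` so silence stays finite), orthonormal DCT-II.
#'
#' @param clip An [audio_clip()].
#' @param n_mfcc Number of coefficients to keep (default 13).
#' @param frame_length,hop_length Analysis frame and hop in samples
#'   (defaults 2048 and 512).
#' @param n_mels Mel bands in the front end (default 128).
#' @param log_floor Power floor before the log (default 1e-10).
#' @return Matrix of shape `n_mfcc x n_frames` with
#'   `n_frames = 1 + floor((length - frame_length)/hop_length)`.
#' @export
compute_mfcc <- function(clip, n_mfcc = 13, frame_length = 2048,
                         hop_length = 512, n_mels = 128, log_floor = 1e-10) {
  check_field(is_scalar_num(n_mfcc) && n_mfcc >= 1, "n_mfcc", "must be >= 1")
  if (length(clip$samples) < frame_length) {
    abort(sprintf("clip (%d samples) shorter than one %d-sample frame",
                  length(clip$samples), frame_length),
          class = "tembo_validation_error")
  }
  fr <- frame_signal(clip$samples, frame_length, hop_length) * hann_window(frame_length)
  spec <- Mod(mvfft(fr))^2
  spec <- spec[seq_len(frame_length %/% 2 + 1), , drop = FALSE]
  fb <- mel_filterbank(clip$sample_rate, frame_length, n_mels)
  melspec <- fb %*% spec
  logmel <- log(pmax(melspec, log_floor))
  dct_matrix(n_mfcc, n_mels) %*% logmel
}

# Constant-Q kernel bank in the FFT domain (Brown & Puckette): one bin per
# semitone from fmin, hann-windowed complex exponentials zero-padded to
# fft_len and transformed. Columns are bins.
cqt_kernels <- function(sr, fmin, n_bins, fft_len) {
  q <- 1 / (2^(1 / 12) - 1)
  K <- matrix(complex(real = 0), nrow = fft_len, ncol = n_bins)
  for (b in seq_len(n_bins)) {
    fk <- fmin * 2^((b - 1) / 12)
    nk <- min(fft_len, round(q * sr / fk))
    w <- hann_window(nk)
    t0 <- (fft_len - nk) %/% 2
    tt <- seq_len(nk) - 1
    kern <- numeric(fft_len) + 0i
    kern[t0 + seq_len(nk)] <- (w / nk) * exp(2i * pi * fk * tt / sr)
    K[, b] <- Conj(fft(kern)) / fft_len
  }
  K
}

#' Chroma constant-Q transform
#'
#' Computes a semitone-resolution constant-Q spectrum (one bin per semitone
#' over `n_octaves` octaves starting at C1, about 32.70 Hz) at the same frame
#' grid as [compute_mfcc()], folds the energy into the 12 pitch classes
#' (bin 0 = C), and normalizes each column to maximum 1. An all-zero frame
#' yields a uniform column (no NaN).
#'
#' @param clip An [audio_clip()].
#' @param frame_length,hop_length Frame grid in samples (defaults 2048, 512);
#'   the CQT analysis window around each frame center may be longer.
#' @param n_octaves Octaves above C1 to analyze (default 6, capped below
#'   Nyquist).
#' @return Matrix of shape `12 x n_frames`.
#' @export
compute_chroma_cqt <- function(clip, frame_length = 2048, hop_length = 512,
                               n_octaves = 6) {
  x <- clip$samples
  sr <- clip$sample_rate
  fmin <- 32.70320  # C1
  if (length(x) < frame_length) {
    abort(sprintf("clip (%d samples) shorter than the %d-sample CQT frame grid",
                  length(x), frame_length), class = "tembo_validation_error")
  }
  n_bins <- n_octaves * 12
  # drop bins at or above Nyquist
  n_bins <- min(n_bins, floor(12 * log2((sr / 2) / fmin)))
  q <- 1 / (2^(1 / 12) - 1)
  need <- round(q * sr / fmin)
  fft_len <- 2^ceiling(log2(min(need, length(x))))
  K <- cqt_kernels(sr, fmin, n_bins, fft_len)
  # frame centers on the MFCC grid
  n_frames <- 1 + floor((length(x) - frame_length) / hop_length)
  centers <- (seq_len(n_frames) - 1) * hop_length + frame_length %/% 2
  half <- fft_len %/% 2
  xp <- c(numeric(half), x, numeric(half))
  starts <- centers + 1L  # start index in padded signal of the fft window
  idx <- outer(seq_len(fft_len) - 1L, starts, "+")
  frames <- matrix(xp[idx], nrow = fft_len)
  X <- mvfft(frames)
  cq <- Mod(t(Conj(K)) %*% X)^2  # |K^H X|^2, bins x frames
  chroma <- matrix(0, 12, n_frames)
  for (b in seq_len(n_bins)) {
    pc <- ((b - 1) %% 12) + 1
    chroma[pc, ] <- chroma[pc, ] + cq[b, ]
  }
  mx <- apply(chroma, 2, max)
  zero <- mx <= 0
  if (any(!zero)) {
    chroma[, !zero] <- sweep(chroma[, !zero, drop = FALSE], 2, mx[!zero], "/")
  }
  if (any(zero)) chroma[, zero] <- 1 / 12
  chroma
}

#' Build a stacked MFCC + chroma feature image
#'
#' Row-concatenates the MFCC matrix and the chroma-CQT matrix computed on a
#' shared frame grid. When a normalizer (from [fit_feature_normalizer()]) is
#' supplied, rows are z-scored with the training-set statistics.
#'
#' @param clip An [audio_clip()].
#' @param n_mfcc,frame_length,hop_length Feature parameters (see
#'   [compute_mfcc()]).
#' @param normalizer Optional normalizer from [fit_feature_normalizer()].
#' @return A `feature_image`: list with `mfcc`, `chroma_cqt`, `stacked`
#'   (`(n_mfcc + 12) x n_frames`) and `label`.
#' @export
build_feature_image <- function(clip, n_mfcc = 13, frame_length = 2048,
                                hop_length = 512, normalizer = NULL) {
  mf <- compute_mfcc(clip, n_mfcc = n_mfcc, frame_length = frame_length,
                     hop_length = hop_length)
  ch <- compute_chroma_cqt(clip, frame_length = frame_length,
                           hop_length = hop_length)
  if (ncol(mf) != ncol(ch)) {
    abort("internal error: MFCC and chroma frame counts differ",
          class = "tembo_internal_error")
  }
  stacked <- rbind(mf, ch)
  if (!is.null(normalizer)) {
    stacked <- (stacked - normalizer$mean) / normalizer$sd
  }
  structure(list(mfcc = mf, chroma_cqt = ch, stacked = stacked,
                 label = clip$label),
            class = "feature_image")
}

#' Fit per-row normalization statistics on training images
#'
#' Statistics are computed from the supplied (training) images only; apply
#' them to validation/test images via the `normalizer` argument of
#' [build_feature_image()] or [normalize_feature_image()].
#'
#' @param images List of `feature_image`s (unnormalized).
#' @return List with per-row `mean` and `sd` vectors.
#' @export
fit_feature_normalizer <- function(images) {
  all <- do.call(cbind, purrr::map(images, "stacked"))
  m <- rowMeans(all)
  s <- apply(all, 1, stats::sd)
  s[s < 1e-12] <- 1
  list(mean = m, sd = s)
}

#' Apply a fitted normalizer to a feature image
#' @param image A `feature_image`.
#' @param normalizer From [fit_feature_normalizer()].
#' @return The normalized `feature_image`.
#' @export
normalize_feature_image <- function(image, normalizer) {
  image$stacked <- (image$stacked - normalizer$mean) / normalizer$sd
  image
}

#' Compute feature images for a whole manifest
#'
#' @param manifest Manifest tibble with `path`, `label`, `split`.
#' @param ... Passed to [build_feature_image()].
#' @return The manifest with a `features` list-column of `feature_image`s
#'   (unnormalized).
#' @export
compute_features <- function(manifest, ...) {
  manifest$features <- purrr::map(seq_len(nrow(manifest)), function(i) {
    clip <- load_audio(manifest$path[i], label = manifest$label[i])
    build_feature_image(clip, ...)
  })
  manifest
}
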