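# Short-time Fourier machinery shared by the augmentation operators and the
# spectrogram features: framing, STFT/ISTFT, and a phase vocoder.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)

# Frame a signal into columns (no centering): starts at 1, 1+hop, ...
# Frame count: 1 + floor((length - frame) / hop).
frame_signal <- function(x, frame, hop) {
  if (length(x) < frame) {
    abort(sprintf("clip too short (%d samples) for a %d-sample frame",
                  length(x), frame), class = "tembo_validation_error")
  }
  starts <- seq(1L, length(x) - frame + 1L, by = hop)
  idx <- outer(seq_len(frame) - 1L, starts, "+")
  matrix(x[idx], nrow = frame)
}

# Complex STFT, frames in columns (full n_fft bins, conjugate-symmetric).
stft <- function(x, n_fft, hop, window = hann_window(n_fft)) {
  fr <- frame_signal(x, n_fft, hop) * window
  mvfft(fr)
}

# Inverse STFT via overlap-add with squared-window normalization.
istft <- function(D, hop, window = hann_window(nrow(D))) {
  n_fft <- nrow(D)
  n_frames <- ncol(D)
  frames <- Re(mvfft(D, inverse = TRUE)) / n_fft
  frames <- frames * window
  n_out <- (n_frames - 1L) * hop + n_fft
  y <- numeric(n_out)
  wsum <- numeric(n_out)
  w2 <- window^2
  for (j in seq_len(n_frames)) {
    s <- (j - 1L) * hop
    y[s + seq_len(n_fft)] <- y[s + seq_len(n_fft)] + frames[, j]
    wsum[s + seq_len(n_fft)] <- wsum[s + seq_len(n_fft)] + w2
  }
  nz <- wsum > 1e-8
  y[nz] <- y[nz] / wsum[nz]
  y
}

wrap_phase <- function(p) p - 2 * pi * round(p / (2 * pi))

# Phase-vocoder time-scale modification. rate > 1 shortens the signal
# (output length ~ length(x) / rate), preserving pitch content.
phase_vocoder <- function(x, rate, n_fft = 2048, hop = NULL) {
  n_fft <- min(n_fft, 2^floor(log2(length(x))))
  hop <- hop %||% (n_fft %/% 4L)
  D <- stft(x, n_fft, hop)
  n_frames <- ncol(D)
  steps <- seq(1, n_frames, by = rate)
  omega <- 2 * pi * hop * (seq_len(n_fft) - 1) / n_fft
  phi <- Arg(D[, 1])
  out <- matrix(complex(real = 0), nrow = n_fft, ncol = length(steps))
  for (j in seq_along(steps)) {
    i0 <- floor(steps[j])
    i1 <- min(i0 + 1L, n_frames)
    a <- steps[j] - i0
    mag <- (1 - a) * Mod(D[, i0]) + a * Mod(D[, i1])
    out[, j] <- mag * exp(1i * phi)
    dphi <- wrap_phase(Arg(D[, i1]) - Arg(D[, i0]) - omega)
    phi <- phi + omega + dphi
  }
  y <- istft(out, hop)
  n_target <- round(length(x) / rate)
  if (length(y) >= n_target) y[seq_len(n_target)] else c(y, numeric(n_target - length(y)))
}

# Resample by a real factor f (> 0): y(t) = x(f * t), cubic interpolation.
# Frequencies scale by f; length scales by 1/f.
resample_by_factor <- function(x, f) {
  n_out <- max(2L, round(length(x) / f))
  pos <- 1 + (seq_len(n_out) - 1) * f
  pos <- pmin(pos, length(x))
  stats::spline(seq_along(x), x, xout = pos, method = "fmm")$y
}
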