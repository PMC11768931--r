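# Internal helpers shared across modules.

# Deterministic 31-bit sub-seed from a master seed and a counter, so that
# clip i's randomness never depends on how many clips precede it.
sub_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(counter) * 16807) %% 2147483647
  as.integer(x)
}

# Validation helper: abort with the offending field name in the message.
check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    abort(sprintf("invalid `%s`: %s", field, msg), class = "tembo_validation_error")
  }
  invisible(TRUE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Dominant frequency of a waveform (Hz) by FFT magnitude peak, DC excluded.
dominant_frequency <- function(samples, sample_rate) {
  n <- length(samples)
  mag <- Mod(fft(samples))[seq_len(floor(n / 2))]
  mag[1] <- 0
  freqs <- (seq_len(floor(n / 2)) - 1) * sample_rate / n
  freqs[which.max(mag)]
}

# Power-spectral centroid of a waveform (Hz).
spectral_centroid <- function(samples, sample_rate) {
  n <- length(samples)
  p <- Mod(fft(samples))[seq_len(floor(n / 2))]^2
  p[1] <- 0
  freqs <- (seq_len(floor(n / 2)) - 1) * sample_rate / n
  if (sum(p) == 0) return(0)
  sum(freqs * p) / sum(p)
}

signal_power <- function(x) mean(x^2)
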