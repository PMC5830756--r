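#' Onset-emphasised amplitude envelope at 100 Hz
#'
#' The raw amplitude envelope is the block mean of the rectified waveform over
#' consecutive 1/100 s blocks. The half-wave rectified first difference of
#' that envelope (onset emphasis) is mixed with the plain envelope as
#' `(1 - lambda_mix) * rectified_diff + lambda_mix * plain`, then smoothed
#' with a Gaussian kernel of standard deviation `gauss_sigma` envelope
#' samples. Output is non-negative at exactly 100 samples per second.
#'
#' @param samples Numeric audio samples (mono; a matrix/stereo pair is summed
#'   across channels first).
#' @param rate_hz Audio sampling rate, >= 8000.
#' @param lambda_mix Weight of the plain envelope in the mix (default 0.1).
#' @param gauss_sigma Gaussian smoothing s.d. in envelope samples (default 3,
#'   i.e. 30 ms).
#' @param target_rate_hz Envelope rate (default 100).
#' @return A [time_series()] at `target_rate_hz` with non-negative values.
#' @export
extract_envelope <- function(samples, rate_hz, lambda_mix = 0.1,
                             gauss_sigma = 3, target_rate_hz = 100) {
  if (is.matrix(samples)) samples <- rowSums(samples)
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty audio")
  if (rate_hz < 8000) stop("audio rate must be >= 8000 Hz")
  block <- rate_hz / target_rate_hz
  n_out <- floor(length(samples) / block)
  if (n_out < 2) stop("audio shorter than two envelope samples")
  idx <- floor((seq_along(samples) - 1) / block) + 1
  keep <- idx <= n_out
  env <- as.numeric(tapply(abs(samples[keep]), idx[keep], mean))
  d <- pmax(c(0, diff(env)), 0)
  mixed <- (1 - lambda_mix) * d + lambda_mix * env
  # Gaussian smoothing, edge-normalized
  half <- ceiling(4 * gauss_sigma)
  k <- stats::dnorm(-half:half, sd = gauss_sigma)
  sm <- function(v) {
    num <- stats::convolve(v, rev(k), type = "open")
    den <- stats::convolve(rep(1, length(v)), rev(k), type = "open")
    (num / den)[seq_along(v) + half]
  }
  time_series(pmax(sm(mixed), 0), target_rate_hz)
}

#' Sliding root-mean-square of an envelope
#'
#' Centred sliding RMS with edge-normalized partial windows, so a constant
#' envelope maps to itself.
#'
#' @param envelope A [time_series()] (typically from [extract_envelope()]).
#' @param window_s Window length in seconds (default 1).
#' @return A [time_series()] at the envelope rate.
#' @export
audio_rms <- function(envelope, window_s = 1) {
  stopifnot(inherits(envelope, "duet_ts"))
  w <- max(1L, round(window_s * envelope$rate_hz))
  kernel <- rep(1, w)
  v <- envelope$values^2
  num <- stats::convolve(v, kernel, type = "open")
  den <- stats::convolve(rep(1, length(v)), kernel, type = "open")
  half <- (w - 1) %/% 2
  # convolution round-off can leave tiny negatives on silent stretches
  out <- sqrt(pmax((num / den)[seq_along(v) + half], 0))
  time_series(out, envelope$rate_hz, envelope$t0)
}

#' Broad-band wavelet energy of the audio envelope
#'
#' Morlet wavelet energy of the envelope averaged over a wide band
#' (0.25-10 Hz by default, reflecting the faster periodicities of audio
#' events relative to ancillary movement).
#'
#' @param envelope A [time_series()] at 100 Hz (any rate with Nyquist above
#'   `high_hz` works).
#' @param low_hz,high_hz Analysis band limits.
#' @param voices Grid density (voices per octave).
#' @param omega0 Morlet centre frequency.
#' @return A [time_series()] of band-mean wavelet energy at the envelope rate.
#' @export
audio_wt_energy <- function(envelope, low_hz = 0.25, high_hz = 10,
                            voices = 20, omega0 = 6) {
  wt <- morlet_wt(envelope, frequency_grid(low_hz, high_hz, voices), omega0)
  band_energy(wt, frequency_band(sqrt(low_hz * high_hz),
                                 low_hz, high_hz * (1 + 1e-9)))
}

# normalized autocorrelation of v at integer lags (lag 0 -> 1)
norm_acf <- function(v, max_lag) {
  v <- v - mean(v)
  denom <- sum(v^2)
  if (denom <= 0) return(rep(0, max_lag))
  n <- length(v)
  vapply(seq_len(max_lag), function(k) {
    sum(v[1:(n - k)] * v[(k + 1):n]) / denom
  }, numeric(1))
}

local_max_idx <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Simplified windowed pulse clarity
#'
#' A deliberately simple index of how strongly the envelope conveys a regular
#' pulse: per sliding window, the normalized autocorrelation of the
#' differentiated envelope is computed over lags 0.25-2 s, and clarity is the
#' height of its maximum local peak, clamped to `[0, 1]`. Windows with no
#' envelope activity score 0. Values are not calibrated against any published
#' pulse-clarity model.
#'
#' @param envelope A [time_series()] (typically 100 Hz).
#' @param window_s Window length in seconds (default 5).
#' @param hop_s Hop between windows in seconds (default 1).
#' @param lag_range_s Autocorrelation lag range in seconds.
#' @return A [time_series()] at `1 / hop_s`, `t0` at the first window centre.
#' @export
pulse_clarity_simple <- function(envelope, window_s = 5, hop_s = 1,
                                 lag_range_s = c(0.25, 2)) {
  stopifnot(inherits(envelope, "duet_ts"), window_s > 2 * lag_range_s[2])
  rate <- envelope$rate_hz
  wn <- round(window_s * rate)
  hopn <- max(1L, round(hop_s * rate))
  d <- pmax(c(0, diff(envelope$values)), 0)
  starts <- seq(1L, length(d) - wn + 1L, by = hopn)
  if (length(starts) < 2) stop("envelope shorter than two analysis windows")
  lag_lo <- max(1L, round(lag_range_s[1] * rate))
  lag_hi <- round(lag_range_s[2] * rate)
  clarity <- vapply(starts, function(s0) {
    seg <- d[s0:(s0 + wn - 1L)]
    if (sum(seg) <= 0) return(0)
    r <- norm_acf(seg, lag_hi)
    peaks <- local_max_idx(r)
    peaks <- peaks[peaks >= lag_lo]
    if (length(peaks) == 0) return(0)
    min(max(max(r[peaks]), 0), 1)
  }, numeric(1))
  time_series(clarity, 1 / hop_s,
              t0 = envelope$t0 + (window_s / 2))
}

#' Envelope event density in events per second
#'
#' Counts local maxima of the envelope above a threshold.
#'
#' @param envelope A [time_series()].
#' @param peak_threshold Minimum peak height.
#' @return Events per second (scalar).
#' @export
event_density <- function(envelope, peak_threshold) {
  stopifnot(inherits(envelope, "duet_ts"))
  v <- envelope$values
  peaks <- local_max_idx(v)
  peaks <- peaks[v[peaks] > peak_threshold]
  length(peaks) / ts_duration(envelope)
}

#' Global tempo estimate from envelope periodicity
#'
#' Tempo is 60 / lag of the dominant normalized autocorrelation peak of the
#' differentiated envelope over lags 0.33-1.0 s (a 60-180 bpm prior). Among
#' peaks within 85% of the strongest one, the shortest lag wins, which
#' resolves the usual beat/bar octave ambiguity toward the beat level.
#'
#' @param envelope A [time_series()].
#' @return Tempo in beats per minute, or `NA` if the envelope is silent.
#' @export
tempo_estimate <- function(envelope) {
  stopifnot(inherits(envelope, "duet_ts"))
  rate <- envelope$rate_hz
  d <- pmax(c(0, diff(envelope$values)), 0)
  if (sum(d) <= 0) return(NA_real_)
  lag_lo <- round(rate / 3)
  lag_hi <- round(rate * 1.0)
  r <- norm_acf(d, lag_hi)
  peaks <- local_max_idx(r)
  peaks <- peaks[peaks >= lag_lo & peaks <= lag_hi]
  if (length(peaks) == 0) {
    peaks <- which.max(r[lag_lo:lag_hi]) + lag_lo - 1L
  }
  near_top <- peaks[r[peaks] >= 0.85 * max(r[peaks])]
  60 / (min(near_top) / rate)
}

#' Read a 16-bit PCM RIFF/WAVE file
#'
#' Minimal reader for canonical uncompressed PCM WAV (mono or stereo); stereo
#' is returned as a two-column matrix.
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (numeric vector or matrix in `[-1, 1]`) and
#'   `rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file")
  rate <- NULL; channels <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      if (fmt[1] != 1) stop("only PCM WAV is supported")
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (bits != 16) stop("only 16-bit PCM is supported")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      data <- readBin(con, "integer", size / 2, 2, endian = "little") / 32768
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(data) || is.null(rate)) stop("malformed WAV file")
  if (channels == 2) data <- matrix(data, ncol = 2, byrow = TRUE)
  list(samples = data, rate_hz = rate)
}

#' Write a 16-bit PCM RIFF/WAVE file
#'
#' @param samples Numeric vector (mono) or two-column matrix (stereo) in
#'   `[-1, 1]`; values are clipped.
#' @param rate_hz Sampling rate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate_hz, path) {
  channels <- if (is.matrix(samples)) ncol(samples) else 1L
  v <- if (is.matrix(samples)) as.vector(t(samples)) else samples
  pcm <- as.integer(round(pmin(pmax(v, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, channels), con, 2, endian = "little")
  writeBin(as.integer(rate_hz), con, 4, endian = "little")
  writeBin(as.integer(rate_hz * channels * 2), con, 4, endian = "little")
  writeBin(c(as.integer(channels * 2), 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
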