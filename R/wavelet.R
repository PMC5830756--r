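#' Log-spaced analysis frequency grid
#'
#' Frequencies spaced evenly in log2, at (at least) `voices` steps per octave,
#' with both endpoints included exactly. This is the grid over which the
#' movement analysis runs (0.3-2.0 Hz by default) and, with wider limits, the
#' audio-envelope analysis (0.25-10 Hz).
#'
#' @param low_hz,high_hz Band limits in Hz, `0 < low_hz < high_hz`.
#' @param voices Voices per octave (grid density), default 20.
#' @return Strictly increasing numeric vector of frequencies in Hz, with
#'   attribute `voices`.
#' @export
frequency_grid <- function(low_hz = 0.3, high_hz = 2.0, voices = 20) {
  stopifnot(low_hz > 0, high_hz > low_hz, voices >= 1)
  n <- ceiling(log2(high_hz / low_hz) * voices)
  f <- exp(seq(log(low_hz), log(high_hz), length.out = n + 1L))
  attr(f, "voices") <- voices
  f
}

#' A frequency band with a nominal centre
#'
#' @param center_hz Nominal centre frequency.
#' @param low_hz,high_hz Band edges; rows with `low_hz <= f < high_hz` belong
#'   to the band (half-open, like every interval in the package).
#' @return A `freq_band` object.
#' @export
frequency_band <- function(center_hz, low_hz, high_hz) {
  stopifnot(low_hz < center_hz, center_hz < high_hz, low_hz > 0)
  structure(list(center_hz = center_hz, low_hz = low_hz, high_hz = high_hz),
            class = "freq_band")
}

#' Build a bank of contiguous log-symmetric bands from centre frequencies
#'
#' Interior edges are geometric midpoints of adjacent centres, so the bank is
#' non-overlapping and contiguous in log frequency. Outer edges default to the
#' log-symmetric extrapolation `c1 * sqrt(c1 / c2)` (and the mirrored rule at
#' the top) but can be pinned explicitly.
#'
#' @param centers_hz Increasing centre frequencies.
#' @param low_edge,high_edge Optional outer edges.
#' @return List of [frequency_band()] objects.
#' @export
band_bank <- function(centers_hz, low_edge = NULL, high_edge = NULL) {
  k <- length(centers_hz)
  stopifnot(k >= 2, !is.unsorted(centers_hz, strictly = TRUE))
  mids <- sqrt(centers_hz[-k] * centers_hz[-1])
  if (is.null(low_edge)) low_edge <- centers_hz[1] * sqrt(centers_hz[1] / centers_hz[2])
  if (is.null(high_edge)) high_edge <- centers_hz[k] * sqrt(centers_hz[k] / centers_hz[k - 1])
  edges <- c(low_edge, mids, high_edge)
  lapply(seq_len(k), function(i) {
    frequency_band(centers_hz[i], edges[i], edges[i + 1])
  })
}

#' The five narrow predictor bands (centres 0.3, 0.4, 0.6, 0.9, 2.0 Hz)
#'
#' Outer edges 0.26 and 2.3 Hz; interior edges are geometric midpoints, so the
#' five bands tile the movement analysis range without overlap.
#' @return List of five [frequency_band()] objects.
#' @export
predictor_bands <- function() {
  band_bank(c(0.3, 0.4, 0.6, 0.9, 2.0), low_edge = 0.26, high_edge = 2.3)
}

#' The broad movement band (0.3-2.0 Hz analysis range)
#'
#' Edges are the outer edges of [predictor_bands()] so the broad band is the
#' exact union of the five narrow bands on any shared grid; on the default
#' 0.3-2.0 Hz grid it selects every row.
#' @return A [frequency_band()].
#' @export
broad_band <- function() frequency_band(sqrt(0.3 * 2.0), 0.26, 2.3)

#' The seven co-occurrence bands (centres 0.29-2.00 Hz)
#'
#' Centres 0.29, 0.33, 0.40, 0.50, 0.67, 1.00, 2.00 Hz with log-symmetric
#' edges; used for the joint density of the two performers' dominant
#' movement frequencies.
#' @return List of seven [frequency_band()] objects.
#' @export
cooccurrence_bands <- function() {
  band_bank(c(0.29, 0.33, 0.40, 0.50, 0.67, 1.00, 2.00))
}

# Morlet scale for a given frequency under the f = omega0 / (2 pi s) mapping.
morlet_scale <- function(freq_hz, omega0) omega0 / (2 * pi * freq_hz)

#' Continuous Morlet wavelet transform
#'
#' FFT-accelerated continuous wavelet transform with an analytic Morlet
#' wavelet of centre frequency `omega0` (default 6), using the scale-frequency
#' mapping `f = omega0 / (2 pi s)`. The wavelet is normalized so that a
#' unit-amplitude sinusoid yields modulus ~1 at its matching frequency row,
#' independent of scale, which makes amplitude profiles directly comparable
#' across frequencies. The signal is zero-padded beyond the truncated kernel
#' support, so coefficients equal a direct time-domain convolution with the
#' sampled kernel (the test-suite oracle) to numerical precision.
#'
#' The cone of influence marks samples closer than `sqrt(2) * s` (the
#' e-folding time of the wavelet envelope) to either edge.
#'
#' @param series A [time_series()].
#' @param grid Frequencies in Hz (see [frequency_grid()]); all must lie at or
#'   below the Nyquist frequency of `series`.
#' @param omega0 Morlet centre frequency (dimensionless), >= 5 for the
#'   analytic approximation to hold.
#' @return A `duet_wt` object: complex `coefficients` (frequency x time),
#'   `grid`, `times`, logical `coi_mask` (TRUE = edge-affected),
#'   `source_rate_hz`, `omega0`.
#' @export
morlet_wt <- function(series, grid = frequency_grid(), omega0 = 6) {
  stopifnot(inherits(series, "duet_ts"))
  x <- series$values
  if (any(!is.finite(x))) stop("morlet_wt: input contains NaN/NA values")
  rate <- series$rate_hz
  dt <- 1 / rate
  freqs <- as.numeric(grid)
  if (is.unsorted(freqs, strictly = TRUE) || any(freqs <= 0)) {
    stop("grid frequencies must be strictly increasing and positive")
  }
  if (max(freqs) > rate / 2 + 1e-12) {
    stop(sprintf("grid frequency %.3g Hz exceeds the Nyquist frequency %.3g Hz",
                 max(freqs), rate / 2))
  }
  if (omega0 < 5) stop("omega0 must be >= 5")
  n <- length(x)
  if (n * dt < 2 / min(freqs)) {
    stop("series must cover at least two periods of the lowest grid frequency")
  }

  scales <- morlet_scale(freqs, omega0)
  # pad past the truncated kernel support (10 scales) to kill circular wrap
  pad <- ceiling(10 * max(scales) * rate)
  npad <- stats::nextn(n + pad, c(2, 3))
  xhat <- stats::fft(c(x, numeric(npad - n)))
  k <- 0:(npad - 1)
  w <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)
  pos <- w > 0

  coef <- matrix(0 + 0i, nrow = length(freqs), ncol = n)
  for (j in seq_along(freqs)) {
    g <- numeric(npad)
    g[pos] <- 2 * exp(-0.5 * (scales[j] * w[pos] - omega0)^2)
    row <- stats::fft(xhat * g, inverse = TRUE) / npad
    coef[j, ] <- row[seq_len(n)]
  }

  times <- ts_times(series)
  edge <- pmin(times - times[1], times[n] - times)
  coi <- outer(sqrt(2) * scales, edge, ">")

  structure(list(coefficients = coef, grid = freqs, times = times,
                 coi_mask = coi, source_rate_hz = rate, omega0 = omega0),
            class = "duet_wt")
}

#' @export
print.duet_wt <- function(x, ...) {
  cat(sprintf("<duet_wt> %d frequencies (%.3g-%.3g Hz) x %d times, omega0 = %g\n",
              length(x$grid), min(x$grid), max(x$grid), length(x$times),
              x$omega0))
  invisible(x)
}

# Bartlett (triangular) smoothing along rows of a (possibly complex) matrix,
# edge-normalized so partial windows keep unit total weight.
bartlett_smooth_rows <- function(m, width) {
  if (width <= 1L) return(m)
  w <- 1 - abs(2 * seq(0, width - 1) / (width - 1) - 1)
  if (sum(w) == 0) return(m)
  sm_vec <- function(v) {
    num <- stats::convolve(v, rev(w), type = "open")
    den <- stats::convolve(rep(1, length(v)), rev(w), type = "open")
    half <- (width - 1) %/% 2
    idx <- seq_along(v) + half
    num[idx] / den[idx]
  }
  out <- m
  for (i in seq_len(nrow(m))) {
    if (is.complex(m)) {
      out[i, ] <- complex(real = sm_vec(Re(m[i, ])),
                          imaginary = sm_vec(Im(m[i, ])))
    } else {
      out[i, ] <- sm_vec(m[i, ])
    }
  }
  out
}

#' Cross-wavelet transform of two wavelet spectra
#'
#' Pointwise product of one spectrum with the complex conjugate of the other:
#' `W_ab = W_a * Conj(W_b)`. Energy is the squared modulus of the cross
#' coefficients after Bartlett (triangular) smoothing along time; phase is the
#' argument of the (by default unsmoothed) cross coefficients, positive when
#' the first performer leads the second. The cone of influence is the union of
#' the input cones.
#'
#' @param wt_a,wt_b `duet_wt` objects on identical grids and time axes.
#' @param smoothing_window_s Bartlett window length in seconds (default 1 s).
#' @param phase_smoothed If TRUE, phase is taken from the smoothed cross
#'   coefficients instead of the raw product.
#' @return A `duet_cwt` object with `cross_coefficients`, `energy`, `phase`,
#'   `grid`, `times`, `coi_mask`, `source_rate_hz`.
#' @export
cross_wavelet <- function(wt_a, wt_b, smoothing_window_s = 1,
                          phase_smoothed = FALSE) {
  stopifnot(inherits(wt_a, "duet_wt"), inherits(wt_b, "duet_wt"))
  if (!isTRUE(all.equal(wt_a$grid, wt_b$grid)) ||
      !isTRUE(all.equal(wt_a$times, wt_b$times)) ||
      wt_a$source_rate_hz != wt_b$source_rate_hz) {
    stop("cross_wavelet: spectra must share grid, times and rate")
  }
  cross <- wt_a$coefficients * Conj(wt_b$coefficients)
  width <- max(1L, round(smoothing_window_s * wt_a$source_rate_hz))
  smoothed <- bartlett_smooth_rows(cross, width)
  structure(list(cross_coefficients = cross,
                 energy = Mod(smoothed)^2,
                 phase = Arg(if (phase_smoothed) smoothed else cross),
                 grid = wt_a$grid, times = wt_a$times,
                 coi_mask = wt_a$coi_mask | wt_b$coi_mask,
                 source_rate_hz = wt_a$source_rate_hz,
                 smoothing_window_s = smoothing_window_s),
            class = "duet_cwt")
}

#' @export
print.duet_cwt <- function(x, ...) {
  cat(sprintf("<duet_cwt> %d frequencies (%.3g-%.3g Hz) x %d times\n",
              length(x$grid), min(x$grid), max(x$grid), length(x$times)))
  invisible(x)
}

band_rows <- function(grid, band) {
  stopifnot(inherits(band, "freq_band"))
  which(grid >= band$low_hz & grid < band$high_hz)
}

energy_matrix <- function(x) {
  if (inherits(x, "duet_cwt")) x$energy else Mod(x$coefficients)^2
}

#' Per-time mean energy within a frequency band
#'
#' For a cross-wavelet result this is the smoothed cross energy (the "CWT
#' energy" predictors); for a single-performer spectrum it is the squared
#' coefficient modulus ("WT energy"). The mean is taken over the grid rows
#' inside `[low_hz, high_hz)`.
#'
#' @param x A `duet_wt` or `duet_cwt`.
#' @param band A [frequency_band()].
#' @param coi_policy `"keep"` retains edge-affected cells (the default; the
#'   predictor pipeline trims 5 s of each recording end instead), `"mask"`
#'   excludes them, yielding `NA` where a whole column is masked.
#' @return A [time_series()] at the source rate (may contain `NA` under
#'   `"mask"`).
#' @export
band_energy <- function(x, band, coi_policy = c("keep", "mask")) {
  coi_policy <- match.arg(coi_policy)
  rows <- band_rows(x$grid, band)
  if (length(rows) == 0L) {
    stop(sprintf("band [%g, %g) Hz contains no grid rows",
                 band$low_hz, band$high_hz))
  }
  e <- energy_matrix(x)[rows, , drop = FALSE]
  if (coi_policy == "mask") {
    e[x$coi_mask[rows, , drop = FALSE]] <- NA_real_
  }
  out <- colMeans(e, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  ts <- time_series(out, x$source_rate_hz, t0 = x$times[1], allow_na = TRUE)
  attr(ts, "coi_policy") <- coi_policy
  ts
}

#' Energy-weighted circular mean phase within a band
#'
#' Summarizes the momentary lead/lag relationship: per time column, the
#' argument of the energy-weighted sum of unit phasors over the band rows.
#' Range (-pi, pi]; positive = first performer leads.
#'
#' @inheritParams band_energy
#' @param x A `duet_cwt`.
#' @return A [time_series()] of phases in radians; `NA` where every band cell
#'   in a column is COI-masked under `"mask"`.
#' @export
band_phase <- function(x, band, coi_policy = c("keep", "mask")) {
  stopifnot(inherits(x, "duet_cwt"))
  coi_policy <- match.arg(coi_policy)
  rows <- band_rows(x$grid, band)
  if (length(rows) == 0L) {
    stop(sprintf("band [%g, %g) Hz contains no grid rows",
                 band$low_hz, band$high_hz))
  }
  w <- x$energy[rows, , drop = FALSE]
  ph <- x$phase[rows, , drop = FALSE]
  if (coi_policy == "mask") w[x$coi_mask[rows, , drop = FALSE]] <- NA_real_
  z <- colSums(w * exp(1i * ph), na.rm = TRUE)
  out <- Arg(z)
  all_masked <- apply(w, 2, function(col) all(is.na(col)))
  out[all_masked] <- NA_real_
  time_series(out, x$source_rate_hz, t0 = x$times[1], allow_na = TRUE)
}

#' Summed single-performer wavelet energy within a band
#'
#' Band energy of each performer's own wavelet transform, summed across the
#' duo: the momentary amount of periodic movement regardless of whether the
#' two periodicities are related.
#'
#' @param wt_a,wt_b `duet_wt` objects on identical grids/times.
#' @inheritParams band_energy
#' @return A [time_series()].
#' @export
summed_wt_energy <- function(wt_a, wt_b, band = broad_band(),
                             coi_policy = c("keep", "mask")) {
  coi_policy <- match.arg(coi_policy)
  ea <- band_energy(wt_a, band, coi_policy)
  eb <- band_energy(wt_b, band, coi_policy)
  time_series(ea$values + eb$values, ea$rate_hz, ea$t0, allow_na = TRUE)
}

#' Joint density of the two performers' dominant frequency bands
#'
#' Per time column, each performer's dominant frequency is the grid row of
#' maximum wavelet energy (ties resolved toward the lowest frequency); the
#' pair of bands containing the two dominant frequencies is counted, and the
#' joint count matrix is normalized to sum 1.
#'
#' @param wt_a,wt_b `duet_wt` objects on identical grids/times.
#' @param bands Non-overlapping bands covering the grid (default the seven
#'   co-occurrence bands).
#' @return A `length(bands) x length(bands)` matrix (rows = performer A),
#'   non-negative, summing to 1, with band centres as dimnames.
#' @export
cooccurrence_density <- function(wt_a, wt_b, bands = cooccurrence_bands()) {
  stopifnot(inherits(wt_a, "duet_wt"), inherits(wt_b, "duet_wt"))
  if (!isTRUE(all.equal(wt_a$grid, wt_b$grid))) {
    stop("cooccurrence_density: spectra must share the frequency grid")
  }
  grid <- wt_a$grid
  row_band <- rep(NA_integer_, length(grid))
  for (i in seq_along(bands)) row_band[band_rows(grid, bands[[i]])] <- i
  if (any(is.na(row_band))) {
    stop("bands must cover every grid frequency")
  }
  dom_a <- row_band[apply(Mod(wt_a$coefficients)^2, 2, which.max)]
  dom_b <- row_band[apply(Mod(wt_b$coefficients)^2, 2, which.max)]
  k <- length(bands)
  counts <- matrix(0, k, k)
  for (t in seq_along(dom_a)) {
    counts[dom_a[t], dom_b[t]] <- counts[dom_a[t], dom_b[t]] + 1
  }
  centers <- vapply(bands, function(b) b$center_hz, numeric(1))
  dimnames(counts) <- list(a = sprintf("%.2f", centers),
                           b = sprintf("%.2f", centers))
  counts / sum(counts)
}

#' Mean and spread of wavelet amplitude across spectra
#'
#' Time-mean coefficient modulus per frequency for each spectrum, then mean
#' and standard deviation across spectra — the aggregate amplitude profile of
#' a set of performers.
#'
#' @param spectra List of `duet_wt` objects sharing a frequency grid.
#' @return Data frame with `frequency_hz`, `mean_amplitude`, `sd_amplitude`
#'   (`NA` for a single spectrum).
#' @export
amplitude_profile <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  grid <- spectra[[1]]$grid
  prof <- vapply(spectra, function(s) {
    stopifnot(isTRUE(all.equal(s$grid, grid)))
    rowMeans(Mod(s$coefficients))
  }, numeric(length(grid)))
  prof <- matrix(prof, nrow = length(grid))
  data.frame(frequency_hz = grid,
             mean_amplitude = rowMeans(prof),
             sd_amplitude = apply(prof, 1, stats::sd))
}

#' Write a wavelet spectrum as a columnar text archive
#'
#' Real and imaginary planes and the COI mask as TSV, plus a JSON metadata
#' block recording the grid, times, omega0 and rate, under a shared basename.
#'
#' @param x A `duet_wt`.
#' @param basename Path prefix; files `<basename>_re.tsv`, `_im.tsv`,
#'   `_mask.tsv`, `_meta.json` are written.
#' @return `basename`, invisibly.
#' @export
write_spectrum <- function(x, basename) {
  stopifnot(inherits(x, "duet_wt"))
  utils::write.table(Re(x$coefficients), paste0(basename, "_re.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(Im(x$coefficients), paste0(basename, "_im.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(x$coi_mask * 1L, paste0(basename, "_mask.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(frequencies_hz = x$grid, times_s = x$times,
               omega0 = x$omega0, source_rate_hz = x$source_rate_hz,
               voices = attr(x$grid, "voices"))
  jsonlite::write_json(meta, paste0(basename, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(basename)
}

#' Read a wavelet spectrum written by [write_spectrum()]
#' @param basename Path prefix used at write time.
#' @return A `duet_wt`.
#' @export
read_spectrum <- function(basename) {
  re <- as.matrix(utils::read.table(paste0(basename, "_re.tsv"), sep = "\t"))
  im <- as.matrix(utils::read.table(paste0(basename, "_im.tsv"), sep = "\t"))
  mask <- as.matrix(utils::read.table(paste0(basename, "_mask.tsv"),
                                      sep = "\t")) > 0
  meta <- jsonlite::read_json(paste0(basename, "_meta.json"),
                              simplifyVector = TRUE)
  coef <- matrix(complex(real = re, imaginary = im), nrow = nrow(re))
  dimnames(mask) <- NULL
  grid <- meta$frequencies_hz
  attr(grid, "voices") <- meta$voices
  structure(list(coefficients = coef, grid = grid, times = meta$times_s,
                 coi_mask = mask, source_rate_hz = meta$source_rate_hz,
                 omega0 = meta$omega0),
            class = "duet_wt")
}
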