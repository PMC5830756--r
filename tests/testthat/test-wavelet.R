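test_that("sinusoid modulus ridge sits at the nearest grid frequency", {
  g <- frequency_grid(0.3, 2.0, 20)
  wt <- morlet_wt(sinusoid_ts(0.5), g)
  nearest <- which.min(abs(g - 0.5))
  cols <- interior_cols(wt)
  ridge <- apply(Mod(wt$coefficients[, cols]), 2, which.max)
  expect_true(all(ridge == nearest))
  # amplitude-preserving normalization: unit sinusoid -> modulus ~ 1 at ridge
  expect_equal(unname(Mod(wt$coefficients[nearest, cols[100]])), 1,
               tolerance = 0.01)
})

test_that("all-zero input yields all-zero coefficients", {
  wt <- morlet_wt(time_series(rep(0, 1000), 25), frequency_grid())
  expect_true(all(Mod(wt$coefficients) == 0))
})

test_that("a two-tone signal shows both ridges at their grid frequencies", {
  g <- frequency_grid(0.3, 2.0, 20)
  t <- seq(0, 120 - 0.04, by = 0.04)
  x <- time_series(sin(2 * pi * 0.4 * t) + sin(2 * pi * 1.0 * t), 25)
  wt <- morlet_wt(x, g)
  col <- Mod(wt$coefficients[, 1500])
  peaks <- which(diff(sign(diff(col))) == -2) + 1
  peak_freqs <- sort(g[peaks[order(-col[peaks])][1:2]])
  step <- g[2] / g[1]
  expect_lt(abs(log(peak_freqs[1] / 0.4)), log(step) * 1.001)
  expect_lt(abs(log(peak_freqs[2] / 1.0)), log(step) * 1.001)
})

test_that("FFT transform matches the direct convolution oracle", {
  set.seed(11)
  rate <- 25
  x <- rnorm(800)
  freqs <- c(0.3, 0.52, 0.9, 1.4, 2.0)
  wt <- morlet_wt(time_series(x, rate), freqs, omega0 = 6)
  oracle <- t(morlet_oracle(x, rate, freqs))
  rel <- sqrt(sum(Mod(wt$coefficients - oracle)^2)) /
    sqrt(sum(Mod(oracle)^2))
  expect_lt(rel, 1e-6)
})

test_that("invalid inputs are rejected with explicit messages", {
  x <- sinusoid_ts(0.5, dur_s = 30)
  expect_error(morlet_wt(x, c(0.5, 20)), "Nyquist")
  bad <- x; bad$values[5] <- NA
  expect_error(morlet_wt(bad, frequency_grid()), "NaN")
  expect_error(morlet_wt(x, frequency_grid(), omega0 = 3), "omega0")
  expect_error(morlet_wt(sinusoid_ts(0.5, dur_s = 4), frequency_grid(0.3, 2)),
               "two periods")
})

test_that("cross-wavelet phase recovers imposed lags with documented sign", {
  g <- frequency_grid(0.3, 2.0, 20)
  f <- 0.5
  a <- sinusoid_ts(f)
  wt_a <- morlet_wt(a, g)
  ridge <- which.min(abs(g - f))
  cols <- interior_cols(wt_a)

  # identical signals: zero phase, energy ridge at f
  cw0 <- cross_wavelet(wt_a, morlet_wt(sinusoid_ts(f), g))
  expect_true(all(abs(cw0$phase[ridge, cols]) < 0.05))
  expect_equal(unname(which.max(rowMeans(cw0$energy[, cols]))), ridge)

  # quarter-period delay of b -> phase +pi/2 (a leads b)
  b <- sinusoid_ts(f, phase = -2 * pi * f * 0.5)  # delayed by 0.5 s
  cw <- cross_wavelet(wt_a, morlet_wt(b, g))
  expect_true(all(abs(cw$phase[ridge, cols] - pi / 2) < 0.05))

  # antiphase -> +-pi with wraparound
  cw2 <- cross_wavelet(wt_a, morlet_wt(sinusoid_ts(f, phase = pi), g))
  expect_true(all(abs(cos(cw2$phase[ridge, cols]) + 1) < 0.01))
})

test_that("cross-wavelet self- and conjugate-symmetry invariants hold", {
  set.seed(3)
  g <- frequency_grid(0.3, 2.0, 10)
  x <- time_series(rnorm(1500), 25)
  y <- time_series(rnorm(1500), 25)
  wx <- morlet_wt(x, g); wy <- morlet_wt(y, g)
  expect_true(all(cross_wavelet(wx, wx)$phase == 0))
  pab <- cross_wavelet(wx, wy)$phase
  pba <- cross_wavelet(wy, wx)$phase
  expect_equal(pab, -pba, tolerance = 1e-12)
  expect_error(cross_wavelet(wx, morlet_wt(time_series(rnorm(1500), 25),
                                           frequency_grid(0.3, 2.0, 12))),
               "share")
})

test_that("unrelated noise yields a small fraction of the coherent energy", {
  set.seed(21)
  g <- frequency_grid(0.4, 0.65, 10)
  a <- sinusoid_ts(0.5, dur_s = 60)
  wa <- morlet_wt(a, g)
  band <- frequency_band(0.5, 0.45, 0.56)
  coherent <- mean(band_energy(cross_wavelet(wa, morlet_wt(a, g)),
                               band)$values)
  noise_e <- replicate(100, {
    b <- time_series(rnorm(length(a$values)), 25)
    mean(band_energy(cross_wavelet(wa, morlet_wt(b, g)), band)$values)
  })
  expect_lt(mean(noise_e), 0.10 * coherent)
})

test_that("band energy localizes, tiles, and honours the COI policy", {
  g <- frequency_grid(0.3, 2.0, 20)
  a <- sinusoid_ts(0.6)
  cw <- cross_wavelet(morlet_wt(a, g), morlet_wt(sinusoid_ts(0.6), g))
  bands <- predictor_bands()
  e06 <- band_energy(cw, bands[[3]])  # centred 0.6
  e20 <- band_energy(cw, bands[[5]])  # centred 2.0
  interior <- seq(200, length(e06$values) - 200)
  expect_true(all(e06$values[interior] > e20$values[interior]))

  # zero input -> zero series
  z <- morlet_wt(time_series(rep(0, 1000), 25), g)
  expect_true(all(band_energy(cross_wavelet(z, z), broad_band())$values == 0))

  # broad band = row-count-weighted combination of the tiling narrow bands
  broad <- band_energy(cw, broad_band())$values
  nrows <- vapply(bands, function(b) sum(g >= b$low_hz & g < b$high_hz),
                  numeric(1))
  narrow <- sapply(bands, function(b) band_energy(cw, b)$values)
  expect_equal(broad, as.vector(narrow %*% nrows) / sum(nrows),
               tolerance = 1e-10)

  expect_error(band_energy(cw, frequency_band(5, 4.9, 5.1)), "no grid rows")

  masked <- band_energy(cw, bands[[1]], coi_policy = "mask")
  expect_true(is.na(masked$values[1]))        # fully edge-affected column
  expect_false(anyNA(band_energy(cw, bands[[1]])$values))
})

test_that("band phase gives the energy-weighted circular mean", {
  g <- frequency_grid(0.3, 2.0, 20)
  f <- 0.6
  wa <- morlet_wt(sinusoid_ts(f), g)
  band <- predictor_bands()[[3]]
  mid <- 1500
  in_phase <- band_phase(cross_wavelet(wa, morlet_wt(sinusoid_ts(f), g)), band)
  expect_lt(abs(in_phase$values[mid]), 0.05)
  anti <- band_phase(cross_wavelet(wa, morlet_wt(sinusoid_ts(f, phase = pi),
                                                 g)), band)
  expect_lt(abs(cos(anti$values[mid]) + 1), 0.01)
  lag <- band_phase(cross_wavelet(
    wa, morlet_wt(sinusoid_ts(f, phase = -2 * pi * f / 4 / f), g)), band)
  expect_lt(abs(lag$values[mid] - pi / 2), 0.05)
  # fully masked column -> NA marker, not zero
  masked <- band_phase(cross_wavelet(wa, morlet_wt(sinusoid_ts(f), g)),
                       band, coi_policy = "mask")
  expect_true(is.na(masked$values[1]))
})

test_that("summed individual energy is additive and frequency-agnostic", {
  g <- frequency_grid(0.3, 2.0, 20)
  wa <- morlet_wt(sinusoid_ts(0.5), g)
  flat <- morlet_wt(time_series(rep(0, 3000), 25), g)
  both_zero <- summed_wt_energy(flat, flat)
  expect_true(all(both_zero$values == 0))
  one_sided <- summed_wt_energy(wa, flat)
  expect_equal(one_sided$values, band_energy(wa, broad_band())$values,
               tolerance = 1e-10)

  # unrelated periodicities: summed WT energy high, cross energy low
  wb <- morlet_wt(sinusoid_ts(1.0), g)
  wa4 <- morlet_wt(sinusoid_ts(0.4), g)
  cols <- 1000:2000
  summed_unrel <- mean(summed_wt_energy(wa4, wb)$values[cols])
  cross_unrel <- mean(band_energy(cross_wavelet(wa4, wb),
                                  broad_band())$values[cols])
  cross_match <- mean(band_energy(cross_wavelet(wa4, morlet_wt(
    sinusoid_ts(0.4), g)), broad_band())$values[cols])
  expect_gt(summed_unrel, 0.5 * cross_match)
  expect_lt(cross_unrel, 0.2 * cross_match)
})

test_that("co-occurrence density concentrates where the generators are", {
  g <- frequency_grid(0.3, 2.0, 20)
  bands <- cooccurrence_bands()
  wa <- morlet_wt(sinusoid_ts(0.67, dur_s = 60), g)
  wb <- morlet_wt(sinusoid_ts(0.67, dur_s = 60), g)
  d <- cooccurrence_density(wa, wb, bands)
  expect_equal(unname(d["0.67", "0.67"]), 1)
  d2 <- cooccurrence_density(morlet_wt(sinusoid_ts(0.5, dur_s = 60), g),
                             wb, bands)
  expect_equal(unname(d2["0.50", "0.67"]), 1)
})

test_that("co-occurrence density is a proper distribution for random input", {
  g <- frequency_grid(0.3, 2.0, 10)
  for (seed in 1:50) {
    set.seed(seed)
    wa <- morlet_wt(time_series(rnorm(500), 25), g)
    wb <- morlet_wt(time_series(rnorm(500), 25), g)
    d <- cooccurrence_density(wa, wb)
    expect_true(all(d >= 0))
    expect_equal(sum(d), 1, tolerance = 1e-12)
  }
})

test_that("amplitude profiles peak at the generator frequency", {
  g <- frequency_grid(0.3, 2.0, 20)
  w75 <- morlet_wt(sinusoid_ts(0.75), g)
  prof <- amplitude_profile(list(w75))
  expect_equal(prof$frequency_hz[which.max(prof$mean_amplitude)],
               g[which.min(abs(g - 0.75))])
  rep3 <- amplitude_profile(list(w75, w75, w75))
  expect_true(all(rep3$sd_amplitude == 0))
  # disjoint peaks -> bimodal mean profile
  w04 <- morlet_wt(sinusoid_ts(0.4), g)
  w15 <- morlet_wt(sinusoid_ts(1.5), g)
  m <- amplitude_profile(list(w04, w15))$mean_amplitude
  loc_max <- which(diff(sign(diff(m))) == -2) + 1
  expect_gte(length(loc_max), 2)
  near <- function(f) any(abs(log(g[loc_max] / f)) < log(g[2] / g[1]) * 1.5)
  expect_true(near(0.4)); expect_true(near(1.5))
})

test_that("total energy scales quadratically with signal amplitude", {
  g <- frequency_grid(0.3, 2.0, 10)
  x <- sinusoid_ts(0.7, dur_s = 60)
  e1 <- sum(Mod(morlet_wt(x, g)$coefficients)^2)
  x3 <- time_series(3 * x$values, x$rate_hz)
  e3 <- sum(Mod(morlet_wt(x3, g)$coefficients)^2)
  expect_equal(e3 / e1, 9, tolerance = 1e-8)
})

test_that("the ridge tracks a chirp's instantaneous frequency", {
  rate <- 25; dur <- 120
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  f0 <- 0.3; f1 <- 2.0
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * dur))
  g <- frequency_grid(0.3, 2.0, 20)
  wt <- morlet_wt(time_series(sin(phase), rate), g)
  f_inst <- f0 + (f1 - f0) * t / dur
  cols <- interior_cols(wt)
  cols <- cols[f_inst[cols] > 0.32 & f_inst[cols] < 1.95]  # ridge on-grid
  ridge_row <- apply(Mod(wt$coefficients[, cols]), 2, which.max)
  nearest_row <- vapply(f_inst[cols],
                        function(f) which.min(abs(log(g / f))), integer(1))
  expect_true(all(abs(ridge_row - nearest_row) <= 1))
})

test_that("spectra survive a columnar-archive round trip", {
  g <- frequency_grid(0.3, 2.0, 10)
  wt <- morlet_wt(sinusoid_ts(0.5, dur_s = 30), g)
  base <- file.path(tempdir(), "spec_rt")
  write_spectrum(wt, base)
  back <- read_spectrum(base)
  expect_equal(back$coefficients, wt$coefficients, tolerance = 1e-12)
  expect_equal(back$coi_mask, wt$coi_mask)
  expect_equal(back$grid, wt$grid, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$omega0, wt$omega0)
})
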