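# Shared fixtures and independent oracles, built in code at test time.

sinusoid_ts <- function(freq_hz, dur_s = 120, rate = 25, phase = 0, amp = 1,
                        t0 = 0) {
  t <- t0 + seq(0, dur_s - 1 / rate, by = 1 / rate)
  time_series(amp * sin(2 * pi * freq_hz * t + phase), rate, t0 = t0)
}

# Direct time-domain convolution with the sampled analytic Morlet kernel:
# W(n) = dt * sum_m x_m * conj(psi_s(t_m - t_n)),
# psi_s(t) = sqrt(2/pi)/s * exp(-t^2 / (2 s^2)) * exp(i omega0 t / s).
# Dense O(n^2) per frequency; independent of the FFT path under test.
morlet_oracle <- function(x, rate, freqs, omega0 = 6) {
  dt <- 1 / rate
  idx <- seq_along(x)
  sapply(freqs, function(f) {
    s <- omega0 / (2 * pi * f)
    dmat <- outer(idx, idx, function(m, n) (m - n) * dt)  # t_m - t_n
    psi_conj <- sqrt(2 / pi) / s * exp(-dmat^2 / (2 * s^2)) *
      exp(-1i * omega0 * dmat / s)
    dt * as.vector(x %*% psi_conj)
  })
}

# interior (non-COI) column indices for the lowest band frequency
interior_cols <- function(wt) {
  which(!apply(wt$coi_mask, 2, any))
}

# discrete analytic signal via the FFT (Hilbert-transform oracle)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

circ_dist <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  abs(d)
}

# movement-only simulated duo -> predictor table (shared by several files)
sim_duo_table <- function(seed, coupling = 0.9, duration_s = 160, ...) {
  cfg <- dyad_sim_config(
    duration_s = duration_s,
    bout_schedule = default_bout_schedule(duration_s, coupling = coupling),
    ...)
  sim <- simulate_dyad(cfg, seed = seed)
  duo <- list(rho_a = sim$rho_a, rho_b = sim$rho_b,
              qom_a = sim$qom_a, qom_b = sim$qom_b,
              envelope = NULL, bouts = sim$truth,
              recording_id = sprintf("sim_%d", seed))
  build_predictor_table(list(duo))
}

# several duos of one session, bout schedules staggered across recordings;
# evaluated with a recording-level split so frame autocorrelation cannot
# leak between train and eval
sim_multi_table <- function(seed, coupling = 0.9, n_duos = 4,
                            duration_s = 160) {
  duos <- lapply(seq_len(n_duos), function(j) {
    sched <- default_bout_schedule(duration_s, coupling = coupling)
    shift <- (j - 1) * 7
    sched$onset_s <- sched$onset_s + shift
    sched$offset_s <- pmin(sched$offset_s + shift, duration_s - 0.5)
    cfg <- dyad_sim_config(duration_s = duration_s, bout_schedule = sched)
    sim <- simulate_dyad(cfg, seed = seed * 100 + j)
    list(rho_a = sim$rho_a, rho_b = sim$rho_b,
         qom_a = sim$qom_a, qom_b = sim$qom_b,
         envelope = NULL, bouts = sim$truth,
         recording_id = sprintf("rec_%d", j))
  })
  build_predictor_table(duos)
}
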