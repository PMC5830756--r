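#' Default bout schedule for a simulated duo
#'
#' Bouts are placed at fixed relative positions through the performance.
#' Non-pulsed style uses five long bouts (median ~11 s, matching free
#' improvisation, where visual coordination episodes are sustained); pulsed
#' style uses nine short bouts (~4.5 s). Shared frequencies cycle through the
#' movement analysis band; pulsed duos favour slower sway plus a fast
#' nod-rate component.
#'
#' @param duration_s Performance duration.
#' @param style `"nonpulsed"` or `"pulsed"`.
#' @param coupling Phase-coupling strength in `[0, 1]` applied to every bout.
#' @param phase_lag_rad Stationary phase lag of performer B behind A.
#' @return Data frame: `onset_s`, `offset_s`, `shared_freq_hz`, `coupling`,
#'   `phase_lag_rad`.
#' @export
default_bout_schedule <- function(duration_s, style = c("nonpulsed", "pulsed"),
                                  coupling = 0.9, phase_lag_rad = 0) {
  style <- match.arg(style)
  if (style == "nonpulsed") {
    rel <- c(0.10, 0.28, 0.46, 0.64, 0.82)
    dur <- c(11, 14, 9, 13, 11) * duration_s / 160
    freqs <- c(0.5, 0.9, 0.4, 0.67, 1.3)
  } else {
    rel <- seq(0.08, 0.88, length.out = 9)
    dur <- rep(4.5, 9) * duration_s / 160
    freqs <- rep(c(0.33, 0.4, 2.0), 3)
  }
  on <- rel * duration_s
  data.frame(onset_s = on, offset_s = pmin(on + dur, duration_s - 1),
             shared_freq_hz = freqs, coupling = coupling,
             phase_lag_rad = phase_lag_rad)
}

default_structure_schedule <- function(duration_s,
                                       style = c("nonpulsed", "pulsed")) {
  style <- match.arg(style)
  seg <- if (style == "nonpulsed") c(joint = 40, solo = 26) else
    c(joint = 48, solo = 8)
  on <- 0; rows <- list(); i <- 0
  while (on < duration_s) {
    i <- i + 1
    ty <- names(seg)[(i - 1) %% 2 + 1]
    off <- min(on + seg[[ty]], duration_s)
    rows[[i]] <- data.frame(onset_s = on, offset_s = off, type = ty)
    on <- off
  }
  do.call(rbind, rows)
}

#' Full parameterization of a simulated duo
#'
#' The generator emulates the statistical structure of improvising-duo
#' recordings: two performers swaying with slowly drifting individual
#' frequencies, episodes (bouts) of shared periodicity with Kuramoto-style
#' phase coupling, slow positional wander, sensor noise, alternating
#' joint/solo structural sections, a pool of noisy annotators, and pulsed
#' (click-train, 132 bpm) vs non-pulsed (sparse-event, ~0.45 events/s,
#' nominal 106 bpm) audio.
#'
#' @param duration_s Performance duration (default 160 s, a typical
#'   recording length).
#' @param rate_hz Video frame rate (default 25).
#' @param pulsed Style flag; switches the default bout/structure schedules,
#'   tempo and audio generator.
#' @param bout_schedule Data frame as returned by [default_bout_schedule()].
#' @param solo_freqs_hz Baseline sway frequencies of the two performers
#'   outside bouts (well separated by default so unrelated periodicity
#'   dominates out-of-bout frames).
#' @param freq_drift_sd Random-walk innovation of the instantaneous
#'   frequency, Hz per sqrt(s).
#' @param amplitude_px Sway amplitude in pixels.
#' @param noise_sd Additive coordinate noise s.d. in pixels.
#' @param harmonic Relative amplitude of the second sway harmonic (waveform
#'   asymmetry; 0 gives pure sinusoidal sway).
#' @param wander_scale Multiplier on the slow positional wander (0 pins the
#'   body centre).
#' @param structure_schedule Data frame `onset_s`, `offset_s`, `type`.
#' @param annotator_model List: `onset_jitter_sd_s`, `miss_prob`,
#'   `false_alarm_rate_per_min`, `n_annotators`.
#' @param tempo_bpm Beat tempo for pulsed audio (132 pulsed / 106 nominal
#'   non-pulsed).
#' @param audio_rate_hz Audio sample rate for [simulate_audio()].
#' @param seed Default seed used when none is passed to the generator
#'   functions.
#' @return A `dyad_sim_config` list.
#' @export
dyad_sim_config <- function(duration_s = 160, rate_hz = 25, pulsed = FALSE,
                            bout_schedule = NULL,
                            solo_freqs_hz = c(0.45, 1.6),
                            freq_drift_sd = 0.02,
                            amplitude_px = 20, noise_sd = 0.8,
                            harmonic = 0.3, wander_scale = 1,
                            structure_schedule = NULL,
                            annotator_model = list(
                              onset_jitter_sd_s = 0.3, miss_prob = 0.1,
                              false_alarm_rate_per_min = 0.2,
                              n_annotators = 3),
                            tempo_bpm = if (pulsed) 132 else 106,
                            audio_rate_hz = 8000, seed = 1L) {
  style <- if (pulsed) "pulsed" else "nonpulsed"
  if (is.null(bout_schedule)) {
    bout_schedule <- default_bout_schedule(duration_s, style)
  }
  if (is.null(structure_schedule)) {
    structure_schedule <- default_structure_schedule(duration_s, style)
  }
  stopifnot(all(bout_schedule$offset_s <= duration_s),
            all(bout_schedule$onset_s < bout_schedule$offset_s),
            all(bout_schedule$coupling >= 0 & bout_schedule$coupling <= 1))
  if (nrow(bout_schedule) > 1 &&
      any(bout_schedule$onset_s[-1] < bout_schedule$offset_s[-nrow(bout_schedule)])) {
    stop("bout schedule must be non-overlapping")
  }
  structure(list(duration_s = duration_s, rate_hz = rate_hz, pulsed = pulsed,
                 bout_schedule = bout_schedule,
                 solo_freqs_hz = solo_freqs_hz,
                 freq_drift_sd = freq_drift_sd,
                 amplitude_px = amplitude_px, noise_sd = noise_sd,
                 harmonic = harmonic, wander_scale = wander_scale,
                 structure_schedule = structure_schedule,
                 annotator_model = annotator_model,
                 tempo_bpm = tempo_bpm, audio_rate_hz = audio_rate_hz,
                 seed = seed),
            class = "dyad_sim_config")
}

# smooth positional wander below the analysis band: spline through knots
slow_wander <- function(tt, knot_spacing_s, sd_px) {
  kt <- seq(min(tt), max(tt) + knot_spacing_s, by = knot_spacing_s)
  stats::spline(kt, stats::rnorm(length(kt), sd = sd_px), xout = tt)$y
}

#' Simulate a dyad of coupled performers
#'
#' Each performer's sway phase advances at an instantaneous frequency that
#' mean-reverts to a baseline (the solo frequency outside bouts; inside a
#' bout, a mixture `(1 - coupling) * solo + coupling * shared`). During a
#' bout, performer B's phase is additionally pulled toward performer A's by a
#' Kuramoto term with strength proportional to the coupling, so coupling 0
#' leaves the performers fully independent. The sway waveform contains a
#' second harmonic (real sway is asymmetric), and body position wanders
#' slowly (below the 0.3 Hz analysis band), which keeps the radial movement
#' signal at the sway fundamental.
#'
#' @param config A [dyad_sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List: `trace_a`, `trace_b` (`movement_trace`), `rho_a`, `rho_b`
#'   (radial signals via [preprocess_trace()]), `qom_a`, `qom_b` (kinematic
#'   quantity-of-motion proxies: per-frame barycentre displacement), `truth`
#'   (a [bout_set()]), `structure` (an `interval_tier`), `config`.
#' @export
simulate_dyad <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "dyad_sim_config"))
  set.seed(seed)
  rate <- config$rate_hz; dt <- 1 / rate
  n <- round(config$duration_s * rate)
  tt <- (seq_len(n) - 1) * dt
  sched <- config$bout_schedule

  in_bout <- integer(n)  # 0 = none, else bout row index
  for (b in seq_len(nrow(sched))) {
    in_bout[tt >= sched$onset_s[b] & tt < sched$offset_s[b]] <- b
  }

  k0 <- 4  # full-coupling phase pull, rad/s
  theta_solo <- 0.2; theta_bout <- 1.2  # frequency mean-reversion, 1/s
  f <- matrix(0, n, 2); phi <- matrix(0, n, 2)
  f[1, ] <- config$solo_freqs_hz
  phi[1, ] <- stats::runif(2, 0, 2 * pi)
  innov <- matrix(stats::rnorm(2 * n, sd = config$freq_drift_sd * sqrt(dt)),
                  n, 2)
  for (i in 2:n) {
    b <- in_bout[i - 1]
    if (b > 0) {
      cpl <- sched$coupling[b]
      base <- (1 - cpl) * config$solo_freqs_hz + cpl * sched$shared_freq_hz[b]
      theta <- theta_bout
      pull <- cpl * k0 * sin(phi[i - 1, 1] - phi[i - 1, 2] -
                               sched$phase_lag_rad[b])
    } else {
      base <- config$solo_freqs_hz
      theta <- theta_solo
      pull <- 0
    }
    f[i, ] <- pmax(0.05, f[i - 1, ] + theta * (base - f[i - 1, ]) * dt +
                     innov[i, ])
    phi[i, ] <- phi[i - 1, ] + 2 * pi * f[i, ] * dt + c(0, pull * dt)
  }

  amp <- config$amplitude_px
  h <- config$harmonic
  ws <- config$wander_scale
  make_trace <- function(p, cx, cy) {
    osc_x <- sin(phi[, p]) + h * sin(2 * phi[, p] + 0.9)
    osc_y <- sin(phi[, p] + 0.6) + h * sin(2 * phi[, p] + 1.5)
    x <- cx + ws * slow_wander(tt, 12, 1.6 * amp) + amp * osc_x +
      stats::rnorm(n, sd = config$noise_sd)
    y <- cy + ws * slow_wander(tt, 12, 0.8 * amp) + 0.4 * amp * osc_y +
      stats::rnorm(n, sd = config$noise_sd)
    structure(list(x = x, y = y, rate_hz = rate, roi = NULL,
                   flagged = logical(n), backend = "simulated"),
              class = "movement_trace")
  }
  trace_a <- make_trace(1, 120, 100)
  trace_b <- make_trace(2, 360, 100)

  qom_proxy <- function(tr) {
    disp <- c(0, sqrt(diff(tr$x)^2 + diff(tr$y)^2))
    time_series(disp, rate)
  }

  truth <- bout_set(sched$onset_s, sched$offset_s, support = NA_integer_,
                    recording_id = sprintf("sim_%d", seed))
  struct <- interval_tier(config$structure_schedule$onset_s,
                          config$structure_schedule$offset_s,
                          label = config$structure_schedule$type,
                          annotator_id = "structure",
                          recording_id = sprintf("sim_%d", seed))
  list(trace_a = trace_a, trace_b = trace_b,
       rho_a = preprocess_trace(trace_a), rho_b = preprocess_trace(trace_b),
       qom_a = qom_proxy(trace_a), qom_b = qom_proxy(trace_b),
       phase = phi, freq = f,
       truth = truth, structure = struct, config = config)
}

#' Simulate noisy annotators of a known bout set
#'
#' Each annotator independently misses each true bout with probability
#' `miss_prob`, jitters retained onsets/offsets with Gaussian noise, and adds
#' Poisson-distributed lone false alarms (log-normal durations, median ~4 s).
#'
#' @param truth A [bout_set()].
#' @param annotator_model List with `onset_jitter_sd_s`, `miss_prob`,
#'   `false_alarm_rate_per_min`, `n_annotators`.
#' @param duration_s Recording duration (bounds for jitter/false alarms).
#' @param seed Integer seed.
#' @return List of `interval_tier` objects, one per annotator.
#' @export
simulate_annotators <- function(truth, annotator_model, duration_s,
                                seed = 1L) {
  set.seed(seed)
  m <- annotator_model
  lapply(seq_len(m$n_annotators), function(a) {
    on <- c(); off <- c()
    for (i in seq_len(nrow(truth))) {
      if (stats::runif(1) < m$miss_prob) next
      o1 <- truth$onset_s[i] + stats::rnorm(1, sd = m$onset_jitter_sd_s)
      o2 <- truth$offset_s[i] + stats::rnorm(1, sd = m$onset_jitter_sd_s)
      o1 <- max(0, o1); o2 <- min(duration_s, o2)
      if (o2 - o1 > 0.2) { on <- c(on, o1); off <- c(off, o2) }
    }
    nfa <- stats::rpois(1, m$false_alarm_rate_per_min * duration_s / 60)
    if (nfa > 0) {
      fa_on <- stats::runif(nfa, 0, duration_s - 1)
      fa_dur <- stats::rlnorm(nfa, log(4), 0.4)
      on <- c(on, fa_on); off <- c(off, pmin(fa_on + fa_dur, duration_s))
    }
    if (length(on) == 0) {
      return(structure(data.frame(onset_s = numeric(0),
                                  offset_s = numeric(0),
                                  label = character(0),
                                  free_text = character(0)),
                       annotator_id = sprintf("annotator_%d", a),
                       recording_id = attr(truth, "recording_id"),
                       class = c("interval_tier", "data.frame")))
    }
    suppressWarnings(interval_tier(on, off, label = "interaction",
                                   annotator_id = sprintf("annotator_%d", a),
                                   recording_id = attr(truth, "recording_id")))
  })
}

#' Render traces as a synthetic blob video
#'
#' Each trace becomes a Gaussian-profile white blob on black, centred on the
#' trace coordinates frame by frame — an end-to-end test substrate for the
#' tracking path.
#'
#' @param traces List of `movement_trace` objects of equal length.
#' @param frame_size `c(height, width)` in pixels.
#' @param blob_radius Gaussian s.d. of the blob profile, pixels.
#' @return List of greyscale frame matrices in `[0, 1]`.
#' @export
render_blob_video <- function(traces, frame_size = c(120, 160),
                              blob_radius = 4) {
  if (inherits(traces, "movement_trace")) traces <- list(traces)
  n <- length(traces[[1]]$x)
  h <- frame_size[1]; w <- frame_size[2]
  ext <- ceiling(4 * blob_radius)
  lapply(seq_len(n), function(i) {
    fr <- matrix(0, h, w)
    for (tr in traces) {
      cx <- tr$x[i]; cy <- tr$y[i]
      xs <- max(0, floor(cx) - ext):min(w - 1, ceiling(cx) + ext)
      ys <- max(0, floor(cy) - ext):min(h - 1, ceiling(cy) + ext)
      if (length(xs) == 0 || length(ys) == 0) next
      blob <- exp(-(outer((ys - cy)^2, (xs - cx)^2, "+")) /
                    (2 * blob_radius^2))
      fr[ys + 1, xs + 1] <- pmin(1, fr[ys + 1, xs + 1] + blob)
    }
    fr
  })
}

#' Simulate performance audio
#'
#' Pulsed style: an isochronous click train at `tempo_bpm` with an accent
#' every four beats (clicks are short decaying noise bursts). Non-pulsed
#' style: sparse Poisson events (~0.45 per second, the event rate typical of
#' free improvisation) with variable amplitude and slower decay.
#'
#' @param config A [dyad_sim_config()].
#' @param seed Integer seed.
#' @return List: `samples` (numeric in `[-1, 1]`), `rate_hz`.
#' @export
simulate_audio <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "dyad_sim_config"))
  set.seed(seed)
  rate <- config$audio_rate_hz
  n <- round(config$duration_s * rate)
  out <- numeric(n)
  add_event <- function(out, t0, amplitude, decay_s) {
    i0 <- floor(t0 * rate) + 1
    len <- min(round(6 * decay_s * rate), n - i0 + 1)
    if (len <= 0 || i0 > n) return(out)
    k <- seq_len(len)
    burst <- amplitude * exp(-k / (decay_s * rate)) *
      stats::rnorm(len, sd = 0.5)
    out[i0:(i0 + len - 1)] <- out[i0:(i0 + len - 1)] + burst
    out
  }
  if (config$pulsed) {
    beat <- 60 / config$tempo_bpm
    onsets <- seq(0.2, config$duration_s - 0.5, by = beat)
    amps <- ifelse(seq_along(onsets) %% 4 == 1, 1.0, 0.6)
    for (i in seq_along(onsets)) {
      out <- add_event(out, onsets[i], amps[i], 0.012)
    }
  } else {
    nev <- stats::rpois(1, 0.45 * config$duration_s)
    onsets <- sort(stats::runif(nev, 0, config$duration_s - 0.5))
    for (t0 in onsets) {
      out <- add_event(out, t0, stats::runif(1, 0.3, 1), 0.05)
    }
  }
  peak <- max(abs(out))
  if (peak > 0) out <- out / peak * 0.9
  list(samples = out, rate_hz = rate)
}
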