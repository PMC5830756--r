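#' Names of the twelve frame-wise predictors
#'
#' Column order is fixed and part of the table contract.
#' @return Character vector of length 12.
#' @export
predictor_columns <- function() {
  c("mov_cwt_energy_broad", "mov_cwt_phase",
    "mov_cwt_energy_0.3", "mov_cwt_energy_0.4", "mov_cwt_energy_0.6",
    "mov_cwt_energy_0.9", "mov_cwt_energy_2.0",
    "mov_wt_energy_any", "movement_quantity",
    "audio_rms", "audio_wt_energy_broad", "audio_pulse_clarity")
}

#' The eight-predictor set surviving screening
#'
#' The twelve predictors minus the four that fail to beat the majority-class
#' baseline in any dataset (cross-wavelet phase, pulse clarity, audio RMS,
#' audio wavelet energy).
#' @return Character vector of length 8.
#' @export
predictor_set_8 <- function() {
  setdiff(predictor_columns(),
          c("mov_cwt_phase", "audio_pulse_clarity", "audio_rms",
            "audio_wt_energy_broad"))
}

#' The five-predictor set predictive on the combined dataset
#' @return Character vector of length 5.
#' @export
predictor_set_5 <- function() {
  c("mov_cwt_energy_broad", "mov_cwt_energy_0.6", "mov_cwt_energy_2.0",
    "mov_cwt_energy_0.9", "movement_quantity")
}

#' Assemble the frame-wise predictor table for a set of duos
#'
#' For each duo, computes the twelve predictors on the movement frame grid:
#' cross-wavelet energy over the broad band and the five narrow bands,
#' broad-band cross-wavelet phase, summed single-performer wavelet energy,
#' summed quantity of motion, and (when an envelope is supplied) audio RMS,
#' broad-band audio wavelet energy and simplified pulse clarity resampled to
#' the frame grid. Binary labels come from the bout set. The first and last
#' `trim_s` seconds of each recording are dropped, frames are decimated by
#' taking every `downsample_factor`-th one, and feature columns are z-scored
#' (jointly over the assembled set by default).
#'
#' @param duos List of duos; each a list with `rho_a`, `rho_b` (radial
#'   [time_series()] at the frame rate), `qom_a`, `qom_b` ([time_series()]),
#'   `envelope` ([time_series()] at 100 Hz or `NULL` for movement-only mode),
#'   `bouts` (a [bout_set()]), `recording_id`.
#' @param bands Narrow predictor bands (default [predictor_bands()]).
#' @param broad The broad movement band.
#' @param trim_s Seconds trimmed from each end (default 5).
#' @param downsample_factor Keep every k-th frame (default 5).
#' @param voices,omega0,smoothing_window_s Wavelet parameters.
#' @param coi_policy Passed to the band summaries (default `"keep"`; edge
#'   trimming handles boundary artefacts).
#' @param zscore `"joint"` (default), `"per_recording"`, or `"none"`.
#' @return Data frame (class `predictor_table`) with the twelve predictor
#'   columns, `label`, `recording_id`, `time_s`; attributes `zscore_means`,
#'   `zscore_sds`, `meta` (parameters), `dropped_na_rows`.
#' @export
build_predictor_table <- function(duos, bands = predictor_bands(),
                                  broad = broad_band(), trim_s = 5,
                                  downsample_factor = 5, voices = 20,
                                  omega0 = 6, smoothing_window_s = 1,
                                  coi_policy = "keep",
                                  zscore = c("joint", "per_recording",
                                             "none")) {
  zscore <- match.arg(zscore)
  grid <- frequency_grid(0.3, 2.0, voices)
  per_duo <- lapply(duos, function(duo) {
    rho_a <- duo$rho_a; rho_b <- duo$rho_b
    rate <- rho_a$rate_hz
    n <- length(rho_a$values)
    stopifnot(abs(n - length(rho_b$values)) <= 1,
              abs(n - length(duo$qom_a$values)) <= 1)
    n <- min(n, length(rho_b$values), length(duo$qom_a$values),
             length(duo$qom_b$values))
    crop <- function(ts) time_series(ts$values[seq_len(n)], ts$rate_hz, ts$t0)
    rho_a <- crop(rho_a); rho_b <- crop(rho_b)
    duration <- n / rate
    wt_a <- morlet_wt(rho_a, grid, omega0)
    wt_b <- morlet_wt(rho_b, grid, omega0)
    cw <- cross_wavelet(wt_a, wt_b, smoothing_window_s)

    cols <- list(
      band_energy(cw, broad, coi_policy)$values,
      band_phase(cw, broad, coi_policy)$values)
    for (b in bands) cols <- c(cols, list(band_energy(cw, b, coi_policy)$values))
    cols <- c(cols, list(
      summed_wt_energy(wt_a, wt_b, broad, coi_policy)$values,
      duo$qom_a$values[seq_len(n)] + duo$qom_b$values[seq_len(n)]))

    if (!is.null(duo$envelope)) {
      env <- duo$envelope
      cols <- c(cols, list(
        ts_resample(audio_rms(env), rate, n = n)$values,
        ts_resample(audio_wt_energy(env), rate, n = n)$values,
        ts_resample(pulse_clarity_simple(env), rate, n = n)$values))
    } else {
      cols <- c(cols, list(rep(NA_real_, n), rep(NA_real_, n),
                           rep(NA_real_, n)))
    }

    label <- binarize_tier(duo$bouts, rate, duration)$values[seq_len(n)]
    df <- as.data.frame(stats::setNames(cols, predictor_columns()))
    df$label <- as.integer(label)
    df$recording_id <- duo$recording_id
    df$time_s <- (seq_len(n) - 1) / rate

    keep <- df$time_s >= trim_s & df$time_s < duration - trim_s
    df <- df[keep, , drop = FALSE]
    df[seq(1, nrow(df), by = downsample_factor), , drop = FALSE]
  })
  out <- do.call(rbind, per_duo)
  rownames(out) <- NULL

  has_audio <- !all(is.na(out$audio_rms))
  feat <- predictor_columns()
  if (!has_audio) {
    out <- out[, setdiff(names(out),
                         c("audio_rms", "audio_wt_energy_broad",
                           "audio_pulse_clarity"))]
    feat <- setdiff(feat, c("audio_rms", "audio_wt_energy_broad",
                            "audio_pulse_clarity"))
  }

  n_before <- nrow(out)
  out <- out[stats::complete.cases(out[, feat]), , drop = FALSE]
  dropped <- n_before - nrow(out)

  means <- rep(0, length(feat)); sds <- rep(1, length(feat))
  names(means) <- names(sds) <- feat
  if (zscore == "joint") {
    for (f in feat) {
      means[f] <- mean(out[[f]]); sds[f] <- stats::sd(out[[f]])
      out[[f]] <- if (sds[f] > 0) (out[[f]] - means[f]) / sds[f] else 0
    }
  } else if (zscore == "per_recording") {
    for (rid in unique(out$recording_id)) {
      rows <- out$recording_id == rid
      for (f in feat) {
        s <- stats::sd(out[[f]][rows])
        out[[f]][rows] <- if (s > 0) {
          (out[[f]][rows] - mean(out[[f]][rows])) / s
        } else 0
      }
    }
  }
  structure(out,
            zscore_means = means, zscore_sds = sds,
            dropped_na_rows = dropped,
            meta = list(trim_s = trim_s,
                        downsample_factor = downsample_factor,
                        voices = voices, omega0 = omega0,
                        smoothing_window_s = smoothing_window_s,
                        coi_policy = coi_policy, zscore = zscore,
                        movement_only = !has_audio,
                        band_edges = lapply(bands, unclass)),
            class = c("predictor_table", "data.frame"))
}

#' Write a predictor table as CSV with a JSON sidecar
#'
#' The CSV has the fixed column header; the sidecar records band edges,
#' wavelet parameters, trimming/downsampling and the z-score means/sds needed
#' to invert standardization.
#'
#' @param table A `predictor_table`.
#' @param path CSV output path; the sidecar is `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_predictor_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- attr(table, "meta")
  meta$zscore_means <- as.list(attr(table, "zscore_means"))
  meta$zscore_sds <- as.list(attr(table, "zscore_sds"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a predictor table written by [write_predictor_table()]
#' @param path CSV path.
#' @return A `predictor_table` data frame (metadata restored from the
#'   sidecar when present).
#' @export
read_predictor_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    attr(df, "meta") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  class(df) <- c("predictor_table", "data.frame")
  df
}
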