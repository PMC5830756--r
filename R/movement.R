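#' Video region of interest
#'
#' 0-based, origin top-left, half-open: pixel columns `[x0, x0 + width)` and
#' rows `[y0, y0 + height)`. Frames are greyscale matrices indexed
#' `[row = y, col = x]` with values in `[0, 1]`.
#'
#' @param x0,y0 Top-left corner, 0-based pixels.
#' @param width,height Extent in pixels (> 0).
#' @param performer_id Optional identifier.
#' @return A `video_roi` object.
#' @export
video_roi <- function(x0, y0, width, height, performer_id = NA_character_) {
  stopifnot(width > 0, height > 0, x0 >= 0, y0 >= 0)
  structure(list(x0 = x0, y0 = y0, width = width, height = height,
                 performer_id = performer_id),
            class = "video_roi")
}

roi_slice <- function(frame, roi) {
  if (roi$y0 + roi$height > nrow(frame) || roi$x0 + roi$width > ncol(frame)) {
    stop("ROI exceeds frame bounds")
  }
  frame[(roi$y0 + 1):(roi$y0 + roi$height),
        (roi$x0 + 1):(roi$x0 + roi$width), drop = FALSE]
}

#' Track the intensity barycentre of an ROI across frames
#'
#' Per frame, the greyscale intensity-weighted centroid of the ROI, in
#' full-frame 0-based pixel coordinates. Frames whose ROI is entirely black
#' carry the previous centroid forward and are flagged.
#'
#' @param frames List of greyscale matrices (`[y, x]`, values in `[0, 1]`),
#'   all the same size; at least 2.
#' @param roi A [video_roi()].
#' @param rate_hz Video frame rate (default 25).
#' @return A `movement_trace`: numeric `x`, `y` (pixels), `rate_hz`, `roi`,
#'   logical `flagged` (carried-forward frames), `backend = "greyscale"`.
#' @export
track_barycentre <- function(frames, roi, rate_hz = 25) {
  stopifnot(is.list(frames), length(frames) >= 2)
  n <- length(frames)
  xs <- numeric(n); ys <- numeric(n); flagged <- logical(n)
  px <- roi$x0 + seq_len(roi$width) - 1   # 0-based pixel centres
  py <- roi$y0 + seq_len(roi$height) - 1
  for (i in seq_len(n)) {
    m <- roi_slice(frames[[i]], roi)
    tot <- sum(m)
    if (tot <= 0) {
      flagged[i] <- TRUE
      if (i == 1) {
        xs[i] <- roi$x0 + (roi$width - 1) / 2
        ys[i] <- roi$y0 + (roi$height - 1) / 2
      } else {
        xs[i] <- xs[i - 1]; ys[i] <- ys[i - 1]
      }
    } else {
      xs[i] <- sum(colSums(m) * px) / tot
      ys[i] <- sum(rowSums(m) * py) / tot
    }
  }
  structure(list(x = xs, y = ys, rate_hz = rate_hz, roi = roi,
                 flagged = flagged, backend = "greyscale"),
            class = "movement_trace")
}

#' @export
print.movement_trace <- function(x, ...) {
  cat(sprintf("<movement_trace> %d frames @ %g Hz (%d flagged)\n",
              length(x$x), x$rate_hz, sum(x$flagged)))
  invisible(x)
}

#' Quantity of motion from frame differencing with adaptive background
#'
#' Per frame, the fraction of ROI pixels that are foreground against a
#' running-exponential background model and whose intensity changed by more
#' than `threshold` since the previous frame. The first frame scores 0; the
#' background is updated as `B <- (1 - bg_rate) * B + bg_rate * F`.
#'
#' @param frames List of greyscale matrices, all the same size.
#' @param roi A [video_roi()].
#' @param threshold Intensity-change threshold in `[0, 1]` (default 0.1).
#' @param bg_rate Background learning rate per frame (default 0.05).
#' @param rate_hz Video frame rate.
#' @param normalize Divide by ROI area (default TRUE) so differently sized
#'   ROIs are comparable; `FALSE` returns raw changed-pixel counts.
#' @return A [time_series()] at the video rate.
#' @export
quantity_of_motion <- function(frames, roi, threshold = 0.1, bg_rate = 0.05,
                               rate_hz = 25, normalize = TRUE) {
  stopifnot(is.list(frames), length(frames) >= 2, threshold > 0)
  n <- length(frames)
  qom <- numeric(n)
  prev <- roi_slice(frames[[1]], roi)
  bg <- prev
  for (i in 2:n) {
    cur <- roi_slice(frames[[i]], roi)
    foreground <- (cur - bg) > threshold
    changed <- abs(cur - prev) > threshold
    qom[i] <- sum(foreground & changed)
    bg <- (1 - bg_rate) * bg + bg_rate * cur
    prev <- cur
  }
  if (normalize) qom <- qom / (roi$width * roi$height)
  out <- time_series(qom, rate_hz)
  attr(out, "normalized") <- normalize
  out
}

#' Preprocess a barycentre trace into the radial movement signal
#'
#' Savitzky-Golay smoothing (order 3, window 5 frames) of the x and y
#' coordinates, conversion to polar coordinates about the trace's time-mean
#' position, reduction to the radial coordinate rho, least-squares linear
#' detrend, and min-max normalization to `[0, 1]`. A constant trace yields an
#' all-zero signal rather than `NaN`.
#'
#' @param trace A `movement_trace`.
#' @param sg_order,sg_length Savitzky-Golay polynomial order and window
#'   length in frames.
#' @return A [time_series()] in `[0, 1]` (the radial signal rho).
#' @export
preprocess_trace <- function(trace, sg_order = 3, sg_length = 5) {
  stopifnot(inherits(trace, "movement_trace"))
  n <- length(trace$x)
  if (n <= sg_length) stop("trace shorter than the smoothing window")
  xs <- signal::sgolayfilt(trace$x, p = sg_order, n = sg_length)
  ys <- signal::sgolayfilt(trace$y, p = sg_order, n = sg_length)
  rho <- sqrt((xs - mean(xs))^2 + (ys - mean(ys))^2)
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), rho)
  rho <- fit$residuals
  rng <- diff(range(rho))
  # a constant trace leaves only numerical noise in rho; do not amplify it
  tol <- 1e-8 * max(1, mean(abs(c(xs, ys))))
  rho <- if (rng > tol) (rho - min(rho)) / rng else rep(0, n)
  time_series(rho, trace$rate_hz)
}
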