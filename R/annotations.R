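#' Labelled interval tier (one annotator's intervals on one recording)
#'
#' Intervals are half-open `[onset, offset)` in seconds, sorted, and
#' non-overlapping within a tier; overlapping input intervals are merged with
#' a warning.
#'
#' @param onset_s,offset_s Numeric vectors of interval bounds (`onset <
#'   offset`).
#' @param label Optional label per interval (e.g. `"interaction"`, `"joint"`,
#'   `"solo"`); overlap merging only merges intervals sharing a label.
#' @param free_text Optional free-text description per interval.
#' @param annotator_id,recording_id Identifiers.
#' @return An `interval_tier`: a data frame of intervals plus identifier
#'   attributes.
#' @export
interval_tier <- function(onset_s, offset_s, label = NA_character_,
                          free_text = NA_character_,
                          annotator_id = NA_character_,
                          recording_id = NA_character_) {
  stopifnot(length(onset_s) == length(offset_s))
  df <- data.frame(onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s),
                   label = rep_len(as.character(label), length(onset_s)),
                   free_text = rep_len(as.character(free_text),
                                       length(onset_s)),
                   stringsAsFactors = FALSE)
  if (any(df$offset_s <= df$onset_s)) stop("intervals need onset < offset")
  df <- df[order(df$onset_s), , drop = FALSE]
  # merge overlapping intervals sharing a label
  if (nrow(df) > 1) {
    merged <- df[1, , drop = FALSE]
    warned <- FALSE
    for (i in 2:nrow(df)) {
      j <- nrow(merged)
      same <- identical(merged$label[j], df$label[i]) ||
        (is.na(merged$label[j]) && is.na(df$label[i]))
      if (same && df$onset_s[i] < merged$offset_s[j]) {
        merged$offset_s[j] <- max(merged$offset_s[j], df$offset_s[i])
        warned <- TRUE
      } else {
        merged <- rbind(merged, df[i, , drop = FALSE])
      }
    }
    if (warned) warning("overlapping intervals merged on load")
    df <- merged
  }
  rownames(df) <- NULL
  structure(df, annotator_id = annotator_id, recording_id = recording_id,
            class = c("interval_tier", "data.frame"))
}

#' A set of aggregated coordination bouts
#'
#' Non-overlapping, sorted intervals with the minimum number of raters that
#' agreed on each retained sample.
#'
#' @param onset_s,offset_s Interval bounds (`onset < offset`).
#' @param support Minimum raters agreeing (metadata).
#' @param recording_id Identifier.
#' @return A `bout_set` data frame.
#' @export
bout_set <- function(onset_s, offset_s, support = NA_integer_,
                     recording_id = NA_character_) {
  df <- data.frame(onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s))
  if (nrow(df) > 0) {
    stopifnot(all(df$offset_s > df$onset_s))
    df <- df[order(df$onset_s), , drop = FALSE]
    if (nrow(df) > 1 && any(df$onset_s[-1] < df$offset_s[-nrow(df)])) {
      stop("bout intervals must be non-overlapping")
    }
  }
  rownames(df) <- NULL
  structure(df, support = support, recording_id = recording_id,
            class = c("bout_set", "data.frame"))
}

#' Binarize an interval tier or bout set onto a sample grid
#'
#' Sample `i` (at time `(i - 1) / rate_hz`) is 1 iff it lies inside any
#' interval, half-open `[onset, offset)`.
#'
#' @param tier An `interval_tier` or `bout_set`.
#' @param rate_hz Sampling rate of the output.
#' @param duration_s Total duration covered.
#' @return A binary [time_series()].
#' @export
binarize_tier <- function(tier, rate_hz, duration_s) {
  n <- max(2L, floor(duration_s * rate_hz))
  tt <- (seq_len(n) - 1) / rate_hz
  out <- numeric(n)
  for (i in seq_len(nrow(tier))) {
    out[tt >= tier$onset_s[i] & tt < tier$offset_s[i]] <- 1
  }
  time_series(out, rate_hz)
}

#' Convert a binary time series back into intervals
#'
#' Runs of 1s become half-open intervals `[t_first, t_last + 1/rate)`.
#'
#' @param x A binary [time_series()].
#' @return Data frame with `onset_s`, `offset_s`.
#' @export
series_to_intervals <- function(x) {
  stopifnot(inherits(x, "duet_ts"))
  v <- x$values > 0.5
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tt <- ts_times(x)
  data.frame(onset_s = tt[starts[keep]],
             offset_s = tt[ends[keep]] + 1 / x$rate_hz)
}

#' Banded asymmetric dynamic time warping of one series onto another
#'
#' Aligns `series_b` onto the time axis of `series_a` using an asymmetric
#' step pattern ((1,0), (1,1), (1,2): every reference sample consumes one
#' output sample) within a Sakoe-Chiba band of `band_s` seconds. The warping
#' path is monotonic and anchored at both ends. `band_s = 0` returns `b`
#' unchanged. Used to absorb small timing discrepancies between annotators
#' before computing agreement.
#'
#' @param series_a,series_b [time_series()] objects at equal rates (binary in
#'   the annotation use, but any numeric works).
#' @param band_s Half-width of the alignment band in seconds.
#' @return `series_b` warped onto `series_a`'s axis (same length as
#'   `series_a`).
#' @export
dtw_align <- function(series_a, series_b, band_s = 2) {
  stopifnot(inherits(series_a, "duet_ts"), inherits(series_b, "duet_ts"),
            band_s >= 0)
  if (series_a$rate_hz != series_b$rate_hz) {
    stop("dtw_align: series must share a sampling rate")
  }
  a <- series_a$values; b <- series_b$values
  n <- length(a); m <- length(b)
  band <- round(band_s * series_a$rate_hz)
  if (band < abs(n - m)) {
    stop("alignment band is narrower than the length difference")
  }
  if (band == 0 && n == m) return(series_b)

  big <- .Machine$double.xmax / 4
  # D[i, j]: cost of aligning a[1..i] with b[1..j]; band-limited over j
  lo <- pmax(1L, seq_len(n) - band)
  hi <- pmin(m, seq_len(n) + band)
  D <- matrix(big, nrow = n, ncol = m)
  P <- matrix(0L, nrow = n, ncol = m)  # predecessor j at step i-1
  D[1, lo[1]:hi[1]] <- abs(a[1] - b[lo[1]:hi[1]])
  for (i in 2:n) {
    for (j in lo[i]:hi[i]) {
      best <- D[i - 1, j]; arg <- j
      if (j > 1 && D[i - 1, j - 1] < best) { best <- D[i - 1, j - 1]; arg <- j - 1L }
      if (j > 2 && D[i - 1, j - 2] < best) { best <- D[i - 1, j - 2]; arg <- j - 2L }
      if (best < big) {
        D[i, j] <- best + abs(a[i] - b[j])
        P[i, j] <- arg
      }
    }
  }
  if (D[n, m] >= big) stop("no admissible warping path within the band")
  path <- integer(n)
  path[n] <- m
  for (i in n:2) path[i - 1] <- P[i, path[i]]
  time_series(b[path], series_a$rate_hz, series_a$t0)
}

#' Cohen's kappa between two binary time series
#'
#' Chance-corrected frame-wise agreement from the 2x2 coincidence table, with
#' the large-sample z statistic under the null of chance agreement.
#'
#' @param a,b Binary [time_series()] objects of equal length, or plain 0/1
#'   vectors.
#' @return List of class `agreement_report`: `kappa`, `z_stat`, `p_value`,
#'   `observed_agreement`, `table` (2x2), `n`.
#' @export
cohens_kappa <- function(a, b) {
  av <- if (inherits(a, "duet_ts")) a$values else as.numeric(a)
  bv <- if (inherits(b, "duet_ts")) b$values else as.numeric(b)
  stopifnot(length(av) == length(bv))
  av <- as.integer(av > 0.5); bv <- as.integer(bv > 0.5)
  n <- length(av)
  tab <- table(factor(av, levels = 0:1), factor(bv, levels = 0:1))
  po <- sum(diag(tab)) / n
  pa <- rowSums(tab) / n  # marginals of a
  pb <- colSums(tab) / n
  pe <- sum(pa * pb)
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  # large-sample variance under H0 (Fleiss, Cohen & Everitt 1969)
  var0 <- (pe + pe^2 - sum(pa * pb * (pa + pb))) / (n * (1 - pe)^2)
  z <- if (var0 > 0) kappa / sqrt(var0) else Inf
  structure(list(kappa = kappa, z_stat = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 observed_agreement = po, table = tab, n = n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> kappa = %.3f (Z = %.2f, p = %.2g), n = %d\n",
              x$kappa, x$z_stat, x$p_value, x$n))
  invisible(x)
}

#' Pairwise agreement across a set of annotator tiers
#'
#' Binarizes every tier, optionally DTW-aligns each pair, and averages
#' Cohen's kappa over all pairings. Both aligned and unaligned kappas are
#' reported.
#'
#' @param tiers List of `interval_tier` objects on one recording.
#' @param rate_hz,duration_s Sampling grid for binarization.
#' @param band_s DTW band half-width in seconds (0 disables alignment).
#' @return List: `mean_kappa`, `mean_kappa_unaligned`, `mean_z`, `pairs`
#'   (per-pair data frame), `alignment_params`.
#' @export
rater_agreement <- function(tiers, rate_hz, duration_s, band_s = 2) {
  stopifnot(length(tiers) >= 2)
  bins <- lapply(tiers, binarize_tier, rate_hz = rate_hz,
                 duration_s = duration_s)
  combs <- utils::combn(length(tiers), 2)
  rows <- apply(combs, 2, function(ij) {
    a <- bins[[ij[1]]]; b <- bins[[ij[2]]]
    raw <- cohens_kappa(a, b)
    al <- if (band_s > 0) cohens_kappa(a, dtw_align(a, b, band_s)) else raw
    c(i = ij[1], j = ij[2], kappa = al$kappa, kappa_unaligned = raw$kappa,
      z = al$z_stat)
  })
  rows <- as.data.frame(t(rows))
  list(mean_kappa = mean(rows$kappa),
       mean_kappa_unaligned = mean(rows$kappa_unaligned),
       mean_z = mean(rows$z),
       pairs = rows,
       alignment_params = list(band_s = band_s, step = "asymmetric"))
}

#' Aggregate annotator tiers into consensus bouts
#'
#' A sample belongs to a bout iff at least `min_raters` annotators marked it;
#' runs of such samples become intervals. Aggregated bouts shorter than
#' `min_duration_s` (default two samples) are discarded as degenerate.
#'
#' @param tiers List of `interval_tier` objects.
#' @param min_raters Minimum agreeing annotators (default 2).
#' @param rate_hz Sampling grid rate.
#' @param duration_s Recording duration.
#' @param min_duration_s Minimum retained bout duration (default `2 /
#'   rate_hz`).
#' @return A [bout_set()].
#' @export
aggregate_bouts <- function(tiers, min_raters = 2, rate_hz = 25,
                            duration_s, min_duration_s = 2 / rate_hz) {
  bins <- lapply(tiers, binarize_tier, rate_hz = rate_hz,
                 duration_s = duration_s)
  votes <- Reduce(`+`, lapply(bins, function(b) b$values))
  consensus <- time_series(as.numeric(votes >= min_raters), rate_hz)
  iv <- series_to_intervals(consensus)
  iv <- iv[iv$offset_s - iv$onset_s >= min_duration_s - 1e-9, , drop = FALSE]
  bout_set(iv$onset_s, iv$offset_s, support = min_raters,
           recording_id = attr(tiers[[1]], "recording_id"))
}

#' Histogram of bout onsets by relative position within structural sections
#'
#' Each bout onset is located within its enclosing structural section
#' (half-open), expressed as a relative position in `[0, 1]`, and binned into
#' `100 / bin_pct` bins (`[0, 5)` ... `[95, 100]` for the default 5% bins),
#' split by section type. Onsets outside any section are dropped and counted.
#'
#' @param bouts A [bout_set()].
#' @param structure An `interval_tier` whose labels are the section types
#'   (e.g. `"joint"`, `"solo"`).
#' @param bin_pct Bin width in percent (default 5).
#' @return Matrix of counts (bins x section types) with attribute `dropped`.
#' @export
onset_position_histogram <- function(bouts, structure, bin_pct = 5) {
  nbins <- as.integer(round(100 / bin_pct))
  types <- unique(structure$label)
  counts <- matrix(0L, nrow = nbins, ncol = length(types),
                   dimnames = list(
                     sprintf("[%g,%g)", bin_pct * (0:(nbins - 1)),
                             bin_pct * (1:nbins)),
                     types))
  dropped <- 0L
  for (on in bouts$onset_s) {
    hit <- which(structure$onset_s <= on & on < structure$offset_s)
    if (length(hit) == 0) { dropped <- dropped + 1L; next }
    hit <- hit[1]
    rel <- (on - structure$onset_s[hit]) /
      (structure$offset_s[hit] - structure$onset_s[hit])
    bin <- min(nbins, floor(rel * nbins) + 1L)
    ty <- match(structure$label[hit], types)
    counts[bin, ty] <- counts[bin, ty] + 1L
  }
  attr(counts, "dropped") <- dropped
  counts
}

#' Two-sample chi-square comparison of onset histograms
#'
#' Homogeneity chi-square over the bins of two count histograms; bins where
#' both histograms are zero are merged out (dropped) first. No continuity
#' correction.
#'
#' @param h1,h2 Count vectors (or single histogram columns) of equal length.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
chi_square_histograms <- function(h1, h2) {
  h1 <- as.numeric(h1); h2 <- as.numeric(h2)
  stopifnot(length(h1) == length(h2))
  keep <- h1 + h2 > 0
  h1 <- h1[keep]; h2 <- h2[keep]
  if (length(h1) < 2) return(list(statistic = 0, df = 0, p_value = 1))
  if (identical(h1, h2)) {
    return(list(statistic = 0, df = length(h1) - 1, p_value = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(rbind(h1, h2), correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Read a tab-delimited annotation export
#'
#' Expects the tab-delimited interval export produced by annotation tools
#' such as ELAN: columns tier, onset (s), offset (s), and optional free text,
#' without a header. Returns one `interval_tier` per tier name.
#'
#' @param path Path to the tab-delimited file.
#' @param recording_id Identifier attached to each tier.
#' @return Named list of `interval_tier` objects.
#' @export
read_elan_tsv <- function(path, recording_id = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          fill = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("malformed annotation file: need >= 3 columns")
  names(df)[1:3] <- c("tier", "onset_s", "offset_s")
  df$text <- if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_
  df$onset_s <- suppressWarnings(as.numeric(df$onset_s))
  df$offset_s <- suppressWarnings(as.numeric(df$offset_s))
  if (any(is.na(df$onset_s)) || any(is.na(df$offset_s))) {
    stop("malformed annotation file: non-numeric interval bounds")
  }
  lapply(split(df, df$tier), function(d) {
    interval_tier(d$onset_s, d$offset_s, label = d$tier,
                  free_text = d$text, annotator_id = d$tier[1],
                  recording_id = recording_id)
  })
}

#' Write a bout set as TSV
#' @param bouts A [bout_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bouts_tsv <- function(bouts, path) {
  utils::write.table(as.data.frame(bouts)[, c("onset_s", "offset_s")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a bout set as JSON
#' @param bouts A [bout_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bouts_json <- function(bouts, path) {
  jsonlite::write_json(list(recording_id = attr(bouts, "recording_id"),
                            support = attr(bouts, "support"),
                            intervals = as.data.frame(bouts)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
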