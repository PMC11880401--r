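# Detection of the active 5CRT span within a recording and its split into
# five chair-rise cycles.
#
# All indices are 1-based; spans and cycles are half-open [start, end), so
# cycle durations partition the test duration exactly.

# Zero-phase 10 Hz low-pass (2nd-order Butterworth, filtered forward and
# backward). Used only to locate landmarks and peaks; stored signals are
# never filtered.
smooth_lowpass <- function(x, rate, cutoff = 10) {
  x <- as.numeric(x)
  if (rate <= 2 * cutoff) return(x)
  bf <- signal::butter(2, cutoff / (rate / 2))
  # replicate the edge values so the zero-phase filter settles outside the
  # region of interest instead of ringing at the boundaries
  p <- min(length(x), max(12L, round(3 * rate / cutoff)))
  xp <- c(rep(x[1], p), x, rep(x[length(x)], p))
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(p + 1):(p + length(x))]
}

# Local maxima (plateau-left-edge aware) of x exceeding min_height whose
# topographic prominence is at least min_prominence. Prominence of a peak is
# its height minus the higher of the two minima separating it from higher
# terrain on each side (the boundary acts as higher terrain).
find_peaks <- function(x, min_height = -Inf, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] &
                x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > min_height]
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    keep[k] <- (h - max(lmin, rmin)) >= min_prominence
  }
  cand[keep]
}

# Robust noise-level estimate: scaled MAD of the residual around the
# smoothed signal.
estimate_noise <- function(x, rate) {
  stats::mad(as.numeric(x) - smooth_lowpass(x, rate))
}

#' Detect the rest-bounded active span of a 5CRT
#'
#' Finds where the force plate leaves its seated rest level before the test
#' and returns to it afterwards. The rest level is the median of the leading
#' (trailing) `min_rest_s` window; samples deviating from it by more than
#' `rest_tol` for at least `min_active_s` are considered activity, and the
#' span runs from the first to the last such activity, with each edge refined
#' to the last/first sample indistinguishable from rest at the recording's
#' own noise level.
#'
#' @param series Body-weight-normalized series (numeric or `crt_normalized`).
#' @param rate Sampling rate in Hz.
#' @param rest_tol Rest-band half-width in a.u. (default 0.05).
#' @param min_rest_s Required rest before and after the test (default 0.5 s).
#' @param min_active_s Shortest excursion counted as activity (default 0.1 s).
#' @return Integer vector `c(start, end)`: 1-based half-open span, with
#'   attributes `rest_level` and `noise_sd`.
#' @export
detect_active_span <- function(series, rate, rest_tol = 0.05,
                               min_rest_s = 0.5, min_active_s = 0.1) {
  v <- if (inherits(series, "crt_normalized")) series$values
       else as.numeric(series)
  check_series(v, "series")
  n <- length(v)
  w <- round(min_rest_s * rate)
  if (n < 2 * w + 2)
    stop("recording shorter than two rest windows")
  med_lead <- stats::median(v[1:w])
  med_tail <- stats::median(v[(n - w + 1):n])
  dev <- pmin(abs(v - med_lead), abs(v - med_tail))
  active <- dev > rest_tol
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sustained <- which(r$values & r$lengths >= round(min_active_s * rate))
  if (length(sustained) == 0)
    stop("no active span found: series never leaves the rest band")
  a <- starts[sustained[1]]
  b <- ends[sustained[length(sustained)]]
  if (a - 1 < w || n - b < w)
    stop("no rest window of min_rest_s found before/after the activity")
  sigma <- stats::mad(v[1:w])
  thr <- max(2 * sigma, 1e-9)
  i <- a - 1L
  while (i > 1L && abs(v[i] - med_lead) > thr) i <- i - 1L
  start <- i
  j <- b + 1L
  while (j < n && abs(v[j] - med_tail) > thr) j <- j + 1L
  end <- j
  structure(c(start = start, end = end),
            rest_level = med_lead, noise_sd = sigma)
}

#' Split the active span into the five chair-rise cycles
#'
#' Each chair rise leaves two prominent force peaks: the seat-off peak of the
#' rise and the sit-down landing peak. Peaks are located on a 10 Hz
#' zero-phase low-pass copy (height above rest + 0.15 a.u., topographic
#' prominence >= 0.18 a.u.) and must alternate seat-off / sit-down, giving
#' exactly `2 * expected` peaks; otherwise segmentation fails with an
#' `crt_incomplete_test_error` carrying the number of complete cycles found.
#' Cycle boundaries are the minima of the smoothed series between the
#' sit-down peak of one cycle and the seat-off peak of the next, refined on
#' the raw samples.
#'
#' @param series Body-weight-normalized series (numeric or `crt_normalized`).
#' @param span Active span from [detect_active_span()].
#' @param rate Sampling rate in Hz.
#' @param expected Number of chair rises the test must contain (default 5).
#' @param peak_height_rise Minimum peak height above the rest level (a.u.).
#' @param peak_prominence Minimum peak prominence (a.u.).
#' @return An object of class `crt_segmentation`: list with `cycles` (data
#'   frame of `cycle`, `start_idx`, `end_idx`, half-open), `test_start_idx`,
#'   `test_end_idx`, `t_grf_s` and `rate`.
#' @export
split_cycles <- function(series, span, rate, expected = 5L,
                         peak_height_rise = 0.15, peak_prominence = 0.18) {
  v <- if (inherits(series, "crt_normalized")) series$values
       else as.numeric(series)
  start <- span[[1]]; end <- span[[2]]
  stopifnot(start >= 1, end <= length(v) + 1, start < end)
  rest <- attr(span, "rest_level")
  if (is.null(rest)) rest <- stats::median(v[seq_len(max(start, 2) - 1)])
  sm <- smooth_lowpass(v, rate)
  idx <- start:(end - 1L)
  pk_local <- find_peaks(sm[idx], min_height = rest + peak_height_rise,
                         min_prominence = peak_prominence)
  peaks <- idx[pk_local]
  if (length(peaks) != 2L * expected) {
    n_complete <- length(peaks) %/% 2L
    stop(incomplete_test_error(n_complete, expected, length(peaks)))
  }
  boundaries <- integer(expected - 1L)
  for (m in seq_len(expected - 1L)) {
    lo <- peaks[2L * m]           # sit-down peak of cycle m
    hi <- peaks[2L * m + 1L]      # seat-off peak of cycle m + 1
    # the junction is the first smoothed local minimum after the landing
    # (the seated pause before the next weight shift), refined on the raw
    # samples
    w <- lo:hi
    sw <- sm[w]
    nl <- length(sw)
    lmins <- which(sw[2:(nl - 1)] < sw[1:(nl - 2)] &
                   sw[2:(nl - 1)] <= sw[3:nl]) + 1L
    lmins <- lmins[sw[lmins] <= rest + 0.1]   # seated pause sits near rest
    jm <- if (length(lmins) > 0) w[lmins[1]] else w[which.min(sw)]
    rw <- max(lo, jm - 5L):min(hi, jm + 5L)
    boundaries[m] <- rw[which.min(v[rw])]
  }
  edges <- c(start, boundaries, end)
  cycles <- data.frame(cycle = seq_len(expected),
                       start_idx = edges[seq_len(expected)],
                       end_idx = edges[seq_len(expected) + 1L])
  structure(list(cycles = cycles,
                 test_start_idx = start,
                 test_end_idx = end,
                 t_grf_s = (end - start) / rate,
                 rate = rate),
            class = "crt_segmentation")
}

incomplete_test_error <- function(detected, expected, n_peaks) {
  structure(class = c("crt_incomplete_test_error", "error", "condition"),
            list(message = sprintf(
                   paste0("incomplete 5CRT: found %d complete chair rise(s) ",
                          "(%d force peaks), expected %d"),
                   detected, n_peaks, expected),
                 call = NULL, detected = detected, expected = expected))
}

#' @export
print.crt_segmentation <- function(x, ...) {
  cat(sprintf(
    "5CRT segmentation: %d cycles, active span [%d, %d), t_GRF = %.2f s\n",
    nrow(x$cycles), x$test_start_idx, x$test_end_idx, x$t_grf_s))
  invisible(x)
}

#' GRF-based test duration
#'
#' Duration of the full active span in seconds, the force-plate analogue of
#' the stopwatch 5CRT time.
#'
#' @param seg A `crt_segmentation`.
#' @return Duration in seconds.
#' @export
grf_duration <- function(seg) {
  stopifnot(inherits(seg, "crt_segmentation"))
  (seg$test_end_idx - seg$test_start_idx) / seg$rate
}

#' Convenience: segment a recording end to end
#'
#' Body-weight-normalizes a recording, detects the active span and splits it
#' into cycles.
#'
#' @param rec A `crt_recording`.
#' @param expected Number of chair rises (default 5).
#' @param ... Passed to [detect_active_span()].
#' @return A `crt_segmentation`.
#' @export
segment_recording <- function(rec, expected = 5L, ...) {
  bw <- normalize_bodyweight(rec)
  span <- detect_active_span(bw$values, rec$sampling_rate_hz, ...)
  split_cycles(bw$values, span, rec$sampling_rate_hz, expected = expected)
}
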