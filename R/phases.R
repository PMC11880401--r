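# Schenkman phase landmarks within one chair-rise cycle and the four
# per-phase normalized force quantities: seat-unloading minimum, seat-off
# peak, stabilization minimum, and the standing-phase force.

#' Locate the Schenkman phase landmarks within a chair-rise cycle
#'
#' Works on one body-weight-normalized cycle (from [split_cycles()]).
#' Locations are found on a 10 Hz zero-phase low-pass copy and refined on the
#' raw samples, so noise-free cycles are recovered exactly:
#' * seat-off peak: maximum over the first `seatoff_frac` of the cycle
#'   (capping the search excludes the sit-down landing peak);
#' * sit-down landing peak (auxiliary): maximum over the final third, used to
#'   bound the windows below;
#' * seat-unloading minimum: last local minimum of the smoothed cycle before
#'   the seat-off peak (falling back to the pre-peak minimum when the
#'   initial weight-shift bump is absent);
#' * stabilization minimum: minimum between the seat-off and sit-down peaks;
#' * standing value: earliest sample reaching the plateau level between the
#'   stabilization minimum and the midpoint from there to the sit-down peak.
#'
#' @param cycle Body-weight-normalized cycle (numeric).
#' @param rate Sampling rate in Hz.
#' @param seatoff_frac Fraction of the cycle searched for the seat-off peak
#'   (default 0.6).
#' @param min_peak_prominence Required prominence of the seat-off peak within
#'   the cycle; below it a `crt_phase_detection_error` is raised.
#' @return Object of class `crt_landmarks`: integer landmark indices
#'   `unload_min_idx`, `seatoff_peak_idx`, `stab_min_idx`, `stand_idx`
#'   (1-based within the cycle) plus the auxiliary `sitdown_peak_idx`.
#' @export
detect_landmarks <- function(cycle, rate, seatoff_frac = 0.6,
                             min_peak_prominence = 0.15) {
  check_series(cycle, "cycle")
  n <- length(cycle)
  if (n < 40) stop(phase_detection_error("cycle too short"))
  sm <- smooth_lowpass(cycle, rate)
  sigma <- stats::mad(cycle - sm)
  # On an (effectively) noise-free cycle the raw extremum inside a small
  # window pinpoints the landmark exactly; under noise the smoothed
  # location is the lower-variance estimate and avoids selecting noise
  # extrema (which would bias amplitudes outward by about one noise SD).
  exact <- sigma < 5e-4
  refine <- function(i0, window, which_fun) {
    w <- max(1L, min(window)):min(n, max(window))
    if (!exact) return(min(max(i0, w[1]), w[length(w)]))
    w <- w[abs(w - i0) <= 3L]
    w[which_fun(cycle[w])]
  }
  # seat-off peak: first prominent smoothed local maximum (the lean bump is
  # below the prominence floor); it must fall inside the search window
  cap <- max(3L, floor(seatoff_frac * n))
  pks <- find_peaks(sm, min_prominence = min_peak_prominence)
  if (length(pks) == 0 || pks[1] >= cap)
    stop(phase_detection_error(
      "no prominent seat-off peak in the search window"))
  so0 <- pks[1]
  so <- refine(so0, 1:cap, which.max)
  # sit-down landing peak (bounds the later windows); when the landing is
  # not prominent (standing force above it), the standing-plateau onset
  # plays its role
  sd0 <- if (length(pks) >= 2) pks[length(pks)]
         else {
           tail_from <- max(so + 1L, floor(0.65 * n))
           tail_from - 1L + which.max(sm[tail_from:n])
         }
  if (sd0 <= so + 2L)
    stop(phase_detection_error("no landing peak after seat-off"))
  sdp <- refine(sd0, (so + 1L):n, which.max)
  # seat-unloading minimum: last smoothed local minimum before seat-off
  pre <- sm[1:so]
  lmin <- if (so >= 4L)
    which(pre[2:(so - 1)] < pre[1:(so - 2)] &
          pre[2:(so - 1)] <= pre[3:so]) + 1L
  else integer(0)
  if (length(lmin) > 0) {
    un0 <- lmin[length(lmin)]
  } else {
    from <- min(max(2L, round(0.03 * n)), so - 1L)
    un0 <- from - 1L + which.min(sm[from:(so - 1L)])
  }
  un <- refine(un0, 1:(so - 1L), which.min)
  # stabilization minimum between the two peaks
  st0 <- so + which.min(sm[(so + 1L):(sd0 - 1L)])
  st <- refine(st0, (so + 1L):(sd0 - 1L), which.min)
  if (cycle[st] >= cycle[so] - 0.1)
    stop(phase_detection_error("no post-peak stabilization minimum"))
  # standing value: earliest raw sample reaching the plateau level within
  # [stab, midpoint(stab, sit-down)]
  hi <- max(st + 1L, floor((st + sdp) / 2))
  wnd <- (st + 1L):hi
  thr_amp <- if (exact) 1e-9 else 2 * sigma
  plateau <- max(cycle[wnd])
  stand <- wnd[which(cycle[wnd] >= plateau - thr_amp)[1]]
  lm <- list(unload_min_idx = as.integer(un),
             seatoff_peak_idx = as.integer(so),
             stab_min_idx = as.integer(st),
             stand_idx = as.integer(stand),
             sitdown_peak_idx = as.integer(sdp))
  if (!(un < so && so < st && st < stand))
    stop(phase_detection_error("landmarks out of order"))
  structure(lm, class = "crt_landmarks")
}

phase_detection_error <- function(msg) {
  structure(class = c("crt_phase_detection_error", "error", "condition"),
            list(message = paste0("phase detection failed: ", msg),
                 call = NULL))
}

#' Per-phase forces at the detected landmarks
#'
#' Reads the series values at the four landmark indices: the signed extremum
#' characteristic of each phase (minima for seat-unloading and stabilization,
#' the seat-off maximum, and the standing-plateau value).
#'
#' @param cycle Body-weight-normalized cycle.
#' @param lm A `crt_landmarks` from [detect_landmarks()].
#' @return Object of class `crt_phase_forces`: named numeric vector with
#'   entries `unload`, `seatoff`, `stab`, `stand` (a.u.).
#' @export
phase_forces <- function(cycle, lm) {
  stopifnot(inherits(lm, "crt_landmarks"))
  check_series(cycle, "cycle")
  out <- c(unload = cycle[lm$unload_min_idx],
           seatoff = cycle[lm$seatoff_peak_idx],
           stab = cycle[lm$stab_min_idx],
           stand = cycle[lm$stand_idx])
  structure(out, class = "crt_phase_forces")
}

#' @export
print.crt_phase_forces <- function(x, ...) {
  cat(sprintf(paste0("Phase forces [a.u.]: unload %.3f, seatoff %.3f, ",
                     "stab %.3f, stand %.3f\n"),
              x[["unload"]], x[["seatoff"]], x[["stab"]], x[["stand"]]))
  invisible(x)
}

#' Phase forces for every cycle of a segmented recording
#'
#' @param rec A `crt_recording`.
#' @param seg Its `crt_segmentation`.
#' @return Data frame: `participant_id`, `cycle`, `unload`, `seatoff`,
#'   `stab`, `stand` (a.u.); rows with failed detection carry `NA` values.
#' @export
phase_report <- function(rec, seg) {
  stopifnot(inherits(rec, "crt_recording"), inherits(seg, "crt_segmentation"))
  bw <- normalize_bodyweight(rec)$values
  rows <- lapply(seq_len(nrow(seg$cycles)), function(k) {
    span <- seg$cycles[k, ]
    cyc <- bw[span$start_idx:(span$end_idx - 1L)]
    pf <- tryCatch(phase_forces(cyc, detect_landmarks(cyc, seg$rate)),
                   crt_phase_detection_error = function(e) NULL)
    if (is.null(pf))
      data.frame(participant_id = rec$participant_id, cycle = k,
                 unload = NA_real_, seatoff = NA_real_, stab = NA_real_,
                 stand = NA_real_)
    else
      data.frame(participant_id = rec$participant_id, cycle = k,
                 unload = pf[["unload"]], seatoff = pf[["seatoff"]],
                 stab = pf[["stab"]], stand = pf[["stand"]])
  })
  do.call(rbind, rows)
}
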