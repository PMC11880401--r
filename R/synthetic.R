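# Synthetic 5CRT force-plate cohort generator with a ground-truth channel.
#
# A chair-rise cycle is synthesized as a shape-preserving piecewise cubic
# Hermite interpolant with zero derivative at every landmark knot (a
# "smoothstep" segment between consecutive knots), so the waveform is
# monotone between knots, never overshoots them, and landmark amplitudes are
# exact local extrema of the sampled series; noise-free round trips through
# the phase detector are then exact. Knots are snapped to the sample grid
# for the same reason.

# Landmark knot positions as fractions of the cycle length. The cycle starts
# and ends in motion (V-shaped junctions between consecutive rises); the
# closing baseline knot at fraction 1.0 is the first sample of the next cycle
# (or of the trailing rest pad).
cycle_fractions <- function() {
  c(base = 0.00, lean = 0.06, unload = 0.15, seatoff = 0.30,
    stab = 0.45, stand = 0.62, stand_end = 0.70, sitdown = 0.85)
}

# Rise of the initial weight-shift bump above the seat-unloading minimum.
# Large enough that the unloading dip is a detectable local minimum, small
# enough that the bump never registers as a chair-rise peak. The bump also
# always clears the seated baseline (trunk flexion loads the feet before
# seat-unloading), so every cycle junction is a genuine local minimum.
LEAN_RISE <- 0.12
LEAN_MIN_ABOVE_BASE <- 0.10

#' Archetype parameters for a 5CRT movement pattern
#'
#' Bundles the per-phase normalized force means/SDs (body-weight units),
#' stopwatch duration distribution, seated baseline and sit-down landing peak
#' that define one movement-pattern archetype of the synthetic cohort.
#'
#' @param label Archetype name.
#' @param unload_mean,unload_sd Seat-unloading minimum force (a.u.).
#' @param seatoff_mean,seatoff_sd Seat-off peak force (a.u.).
#' @param stab_mean,stab_sd Stabilization minimum force (a.u.).
#' @param stand_mean,stand_sd Standing-phase force (a.u.).
#' @param stopwatch_mean_s,stopwatch_sd_s Stopwatch 5CRT duration (s).
#' @param sit_baseline Seated foot load (a.u., strictly between 0 and 1).
#' @param sitdown_peak Sit-down landing transient peak (a.u.).
#' @return An object of class `crt_archetype`.
#' @export
crt_archetype <- function(label, unload_mean, unload_sd, seatoff_mean,
                          seatoff_sd, stab_mean, stab_sd, stand_mean,
                          stand_sd, stopwatch_mean_s, stopwatch_sd_s,
                          sit_baseline = 0.45, sitdown_peak = 1.20) {
  sds <- c(unload_sd, seatoff_sd, stab_sd, stand_sd, stopwatch_sd_s)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  if (!(seatoff_mean > 1 && 1 > stab_mean))
    stop("archetype must satisfy seatoff_mean > 1 > stab_mean")
  if (!(sit_baseline > 0 && sit_baseline < 1))
    stop("sit_baseline must lie strictly between 0 and 1")
  if (stopwatch_mean_s <= 0) stop("stopwatch_mean_s must be positive")
  structure(list(label = label,
                 unload_mean = unload_mean, unload_sd = unload_sd,
                 seatoff_mean = seatoff_mean, seatoff_sd = seatoff_sd,
                 stab_mean = stab_mean, stab_sd = stab_sd,
                 stand_mean = stand_mean, stand_sd = stand_sd,
                 stopwatch_mean_s = stopwatch_mean_s,
                 stopwatch_sd_s = stopwatch_sd_s,
                 sit_baseline = sit_baseline, sitdown_peak = sitdown_peak),
            class = "crt_archetype")
}

#' The two calibrated movement-pattern archetypes
#'
#' Archetype 1 is the fast, low-stabilization-force pattern (stabilization
#' dip 0.39 +/- 0.16 a.u., stopwatch 9.84 +/- 1.41 s); archetype 2 is the
#' slower, high-stabilization-force pattern (0.69 +/- 0.13 a.u.,
#' 12.59 +/- 2.47 s). Seat-unloading, seat-off and standing forces differ
#' only marginally between the two, which is what makes the stabilization
#' phase the discriminating feature.
#'
#' @return List of two `crt_archetype` objects.
#' @export
default_archetypes <- function() {
  list(
    crt_archetype("archetype_1",
                  unload_mean = 0.50, unload_sd = 0.18,
                  seatoff_mean = 1.16, seatoff_sd = 0.13,
                  stab_mean = 0.39, stab_sd = 0.16,
                  stand_mean = 1.04, stand_sd = 0.09,
                  stopwatch_mean_s = 9.84, stopwatch_sd_s = 1.41),
    crt_archetype("archetype_2",
                  unload_mean = 0.55, unload_sd = 0.17,
                  seatoff_mean = 1.15, seatoff_sd = 0.12,
                  stab_mean = 0.69, stab_sd = 0.13,
                  stand_mean = 1.01, stand_sd = 0.067,
                  stopwatch_mean_s = 12.59, stopwatch_sd_s = 2.47)
  )
}

#' Cohort generation configuration
#'
#' @param n_per_archetype Integer vector, participants per archetype
#'   (default `c(72, 100)`).
#' @param sampling_rate_hz Force-plate sampling rate (default 200 Hz).
#' @param noise_sd Additive Gaussian sensor/soft-tissue noise on the
#'   body-weight-normalized signal (a.u., default 0.008, i.e. about 0.8% of
#'   body weight).
#' @param within_participant_sd_scale Cycle-to-cycle amplitude jitter as a
#'   fraction of the between-participant SD (default 0.3).
#' @param rest_pad_s Seated rest before and after the test (s, default 1).
#' @param grf_slope,grf_intercept Linear relation mapping stopwatch duration
#'   to force-plate-labeled duration, `t_GRF = slope * t_stopwatch +
#'   intercept` (defaults 0.89 and 2.86 s).
#' @param grf_noise_sd Residual SD around that relation (s, default 0.3).
#' @param seed Master seed; every participant draws from a substream derived
#'   from it, so cohorts are reproducible and order-independent.
#' @return An object of class `crt_cohort_config`.
#' @export
cohort_config <- function(n_per_archetype = c(72L, 100L),
                          sampling_rate_hz = 200,
                          noise_sd = 0.008,
                          within_participant_sd_scale = 0.3,
                          rest_pad_s = 1.0,
                          grf_slope = 0.89,
                          grf_intercept = 2.86,
                          grf_noise_sd = 0.3,
                          seed = 42L) {
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  if (any(n_per_archetype < 1)) stop("n_per_archetype entries must be >= 1")
  if (rest_pad_s <= 0) stop("rest_pad_s must be positive")
  if (noise_sd < 0 || grf_noise_sd < 0) stop("noise SDs must be >= 0")
  if (within_participant_sd_scale < 0 || within_participant_sd_scale > 1)
    stop("within_participant_sd_scale must lie in [0, 1]")
  structure(list(n_per_archetype = as.integer(n_per_archetype),
                 sampling_rate_hz = sampling_rate_hz,
                 noise_sd = noise_sd,
                 within_participant_sd_scale = within_participant_sd_scale,
                 rest_pad_s = rest_pad_s,
                 grf_slope = grf_slope,
                 grf_intercept = grf_intercept,
                 grf_noise_sd = grf_noise_sd,
                 seed = as.integer(seed)),
            class = "crt_cohort_config")
}

#' Synthesize one chair-rise cycle
#'
#' Generates the body-weight-normalized Fz waveform of a single
#' sit-to-stand-to-sit cycle: seated baseline, brief weight-shift loading
#' bump, seat-unloading minimum, seat-off peak, stabilization minimum,
#' standing plateau, sit-down landing peak, and return to baseline. The
#' waveform is a monotone (shape-preserving) Hermite interpolant through
#' landmark knots snapped to the sample grid, so each landmark amplitude is
#' the exact signal value at its knot sample and no overshoot beyond the
#' landmark extrema can occur between knots.
#'
#' @param amplitudes Named numeric vector or list with entries `unload`,
#'   `seatoff`, `stab`, `stand` (a.u.).
#' @param duration_s Cycle duration in seconds (> 0).
#' @param rate Sampling rate in Hz (> 0).
#' @param noise_sd Additive Gaussian noise SD (a.u.); uses the current RNG
#'   stream.
#' @param sit_baseline Seated baseline force (a.u.).
#' @param sitdown_peak Sit-down landing peak force (a.u.).
#' @return Numeric series of length `round(duration_s * rate)` with attribute
#'   `landmarks`: a data frame of landmark names, 1-based sample indices and
#'   noise-free amplitudes.
#' @export
synth_cycle <- function(amplitudes, duration_s, rate, noise_sd = 0,
                        sit_baseline = 0.45, sitdown_peak = 1.20) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  a <- as.list(amplitudes)
  need <- c("unload", "seatoff", "stab", "stand")
  if (!all(need %in% names(a)))
    stop("amplitudes must name unload, seatoff, stab and stand")
  vals <- unlist(a[need])
  if (!all(is.finite(vals))) stop("amplitudes must be finite")
  L <- round(duration_s * rate)
  if (L < 40) stop("cycle too short to carry its landmarks (need >= 40 samples)")
  fr <- cycle_fractions()
  knot_idx <- round(fr * L)                  # 0-based sample offsets
  knot_val <- c(base = sit_baseline,
                lean = max(a$unload + LEAN_RISE,
                           sit_baseline + LEAN_MIN_ABOVE_BASE),
                unload = a$unload,
                seatoff = a$seatoff,
                stab = a$stab,
                stand = a$stand,
                stand_end = a$stand,
                sitdown = sitdown_peak)
  if (any(diff(knot_idx) <= 0)) stop("cycle too short for distinct landmarks")
  # closing knot: baseline at the (unsampled) start of the next cycle.
  # Interior knots are landmark extrema and get zero slope (no overshoot);
  # the opening/closing baseline knots get three times the adjacent secant
  # (the Fritsch-Carlson monotonicity bound), so motion starts and ends with
  # a detectable onset.
  xs <- c(knot_idx, L)
  ys <- c(knot_val, sit_baseline)
  d <- rep(0, length(xs))
  d[1] <- 3 * (ys[2] - ys[1]) / (xs[2] - xs[1])
  nk <- length(xs)
  d[nk] <- 3 * (ys[nk] - ys[nk - 1]) / (xs[nk] - xs[nk - 1])
  series <- unname(hermite_interp(xs, ys, d, 0:(L - 1)))
  if (noise_sd > 0) series <- series + stats::rnorm(L, 0, noise_sd)
  lm_names <- c("unload", "seatoff", "stab", "stand", "sitdown")
  attr(series, "landmarks") <- data.frame(
    name = lm_names,
    idx = unname(knot_idx[lm_names]) + 1L,
    value = unname(knot_val[lm_names]))
  series
}

# C1 piecewise cubic Hermite through (xs, ys) with prescribed knot slopes d.
# With slopes of 0 or twice the secant it is monotone on every segment, so
# knot values are exact extrema of the curve.
hermite_interp <- function(xs, ys, d, xout) {
  seg <- findInterval(xout, xs, rightmost.closed = TRUE)
  seg[seg < 1] <- 1L
  seg[seg >= length(xs)] <- length(xs) - 1L
  w <- xs[seg + 1L] - xs[seg]
  u <- (xout - xs[seg]) / w
  h00 <- (1 + 2 * u) * (1 - u)^2
  h10 <- u * (1 - u)^2
  h01 <- u^2 * (3 - 2 * u)
  h11 <- u^2 * (u - 1)
  h00 * ys[seg] + h10 * w * d[seg] + h01 * ys[seg + 1L] +
    h11 * w * d[seg + 1L]
}

# Draw participant-level landmark amplitudes for an archetype, redrawing the
# joint vector until it describes a physically coherent chair rise:
# a distinct seat-off peak above both flanking minima, a stabilization dip
# below the standing force, and positive forces throughout.
draw_amplitudes <- function(arch, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    u <- stats::rnorm(1, arch$unload_mean, arch$unload_sd)
    so <- stats::rnorm(1, arch$seatoff_mean, arch$seatoff_sd)
    st <- stats::rnorm(1, arch$stab_mean, arch$stab_sd)
    sd_ <- stats::rnorm(1, arch$stand_mean, arch$stand_sd)
    ok <- (so - u >= 0.22) && (so - st >= 0.22) && (sd_ - st >= 0.10) &&
      (st >= 0.05) && (u >= 0.05) && (sd_ > 0)
    if (ok)
      return(c(unload = u, seatoff = so, stab = st, stand = sd_))
  }
  stop("could not draw coherent landmark amplitudes")
}

# Apply the same coherence margins to cycle-level jittered amplitudes by
# clamping (jitter is small; clamping keeps detectability without redrawing).
clamp_cycle_amplitudes <- function(amp) {
  amp["stab"] <- max(amp["stab"], 0.03)
  amp["unload"] <- max(amp["unload"], 0.03)
  amp["seatoff"] <- max(amp["seatoff"],
                        amp["stab"] + 0.20, amp["unload"] + 0.20)
  amp["stand"] <- max(amp["stand"], amp["stab"] + 0.08)
  amp
}

#' Synthesize one participant's 5CRT recording
#'
#' Draws participant-level landmark amplitudes, a stopwatch duration and a
#' force-plate (GRF) test duration via the configured linear relation, splits
#' the GRF duration into `n_cycles` cycle durations with small multiplicative
#' jitter, re-jitters the amplitudes per cycle, assembles the cycles between
#' seated rest pads, and de-normalizes to Newtons with a drawn body mass so
#' that downstream body-weight normalization is exercised. Uses the current
#' RNG stream; seed before calling for reproducibility.
#'
#' @param arch A `crt_archetype`.
#' @param cfg A `crt_cohort_config`.
#' @param participant_id Identifier stored in the recording and truth record.
#' @param n_cycles Number of chair rises (default 5).
#' @return List with `recording` (a [crt_recording()]) and `truth` (ground
#'   truth: archetype, stopwatch and GRF durations, 1-based half-open test
#'   span, cycle start indices, and per-cycle landmark indices/amplitudes).
#' @export
synth_participant <- function(arch, cfg, participant_id = "P1", n_cycles = 5L) {
  stopifnot(inherits(arch, "crt_archetype"),
            inherits(cfg, "crt_cohort_config"))
  rate <- cfg$sampling_rate_hz
  amp <- draw_amplitudes(arch)
  t_sw <- redraw_positive(function() stats::rnorm(1, arch$stopwatch_mean_s,
                                                  arch$stopwatch_sd_s),
                          lower = 3)
  t_grf <- redraw_positive(function() cfg$grf_slope * t_sw +
                             cfg$grf_intercept +
                             stats::rnorm(1, 0, cfg$grf_noise_sd),
                           lower = 0.5 * n_cycles)
  w <- exp(stats::rnorm(n_cycles, 0, 0.04))
  durs <- t_grf * w / sum(w)
  jit <- cfg$within_participant_sd_scale *
    c(unload = arch$unload_sd, seatoff = arch$seatoff_sd,
      stab = arch$stab_sd, stand = arch$stand_sd)
  cycles <- vector("list", n_cycles)
  cyc_amps <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    ak <- clamp_cycle_amplitudes(amp + stats::rnorm(4, 0, jit))
    cyc_amps[[k]] <- ak
    cycles[[k]] <- synth_cycle(ak, durs[k], rate, noise_sd = 0,
                               sit_baseline = arch$sit_baseline,
                               sitdown_peak = arch$sitdown_peak)
  }
  pad_n <- round(cfg$rest_pad_s * rate)
  body <- unlist(lapply(cycles, as.numeric))
  values <- c(rep(arch$sit_baseline, pad_n), body,
              rep(arch$sit_baseline, pad_n))
  if (cfg$noise_sd > 0)
    values <- values + stats::rnorm(length(values), 0, cfg$noise_sd)
  mass <- min(max(stats::rnorm(1, 75.1, 13.4), 45), 130)
  sex <- if (stats::runif(1) < 0.42) "m" else "f"
  g <- 9.81
  rec <- crt_recording(participant_id = participant_id,
                       sampling_rate_hz = rate,
                       fz_raw = values * mass * g,
                       mass_kg = mass, sex = sex, stopwatch_s = t_sw)
  lens <- vapply(cycles, length, 0L)
  starts <- cumsum(c(pad_n + 1L, lens))       # 1-based; last = end (half-open)
  lmk <- do.call(rbind, lapply(seq_len(n_cycles), function(k) {
    lm <- attr(cycles[[k]], "landmarks")
    data.frame(cycle = k, name = lm$name,
               idx = lm$idx + starts[k] - 1L, value = lm$value)
  }))
  truth <- list(participant_id = participant_id,
                archetype_label = arch$label,
                t_stopwatch_s = t_sw,
                t_grf_s = t_grf,
                t_grf_realized_s = sum(lens) / rate,
                test_start_idx = starts[1],
                test_end_idx = starts[n_cycles + 1],
                cycle_start_idx = starts[seq_len(n_cycles)],
                cycle_lengths = lens,
                landmarks = lmk,
                amplitudes = amp,
                cycle_amplitudes = cyc_amps,
                mass_kg = mass, sex = sex)
  list(recording = rec, truth = truth)
}

redraw_positive <- function(draw, lower, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    v <- draw()
    if (v > lower) return(v)
  }
  stop("could not draw a positive duration")
}

#' Synthesize a 5CRT cohort
#'
#' Generates `sum(cfg$n_per_archetype)` participants, each from its archetype,
#' with per-participant RNG substreams derived from the master seed (the same
#' seed always yields an identical cohort, independent of evaluation order).
#'
#' @param cfg A `crt_cohort_config`.
#' @param archetypes List of `crt_archetype` objects, one per entry of
#'   `cfg$n_per_archetype` (default [default_archetypes()]).
#' @return An object of class `crt_cohort`: list with `recordings`, `truth`
#'   (parallel lists) and `config`.
#' @export
synth_cohort <- function(cfg = cohort_config(),
                         archetypes = default_archetypes()) {
  stopifnot(inherits(cfg, "crt_cohort_config"))
  if (length(archetypes) != length(cfg$n_per_archetype))
    stop("need one archetype per entry of n_per_archetype")
  n_tot <- sum(cfg$n_per_archetype)
  arch_of <- rep(seq_along(archetypes), cfg$n_per_archetype)
  set.seed(cfg$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  ids <- sprintf("P%03d", seq_len(n_tot))
  recs <- vector("list", n_tot)
  truths <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    set.seed(sub_seeds[i])
    out <- synth_participant(archetypes[[arch_of[i]]], cfg,
                             participant_id = ids[i])
    recs[[i]] <- out$recording
    truths[[i]] <- out$truth
  }
  structure(list(recordings = recs, truth = truths, config = cfg),
            class = "crt_cohort")
}

#' @export
print.crt_cohort <- function(x, ...) {
  labs <- vapply(x$truth, `[[`, "", "archetype_label")
  cat(sprintf("Synthetic 5CRT cohort: %d participants (%s)\n",
              length(x$recordings),
              paste(sprintf("%s n=%d", names(table(labs)), table(labs)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.crt_archetype <- function(x, ...) {
  cat(sprintf(paste0("5CRT archetype '%s': unload %.2f+/-%.2f, seatoff ",
                     "%.2f+/-%.2f, stab %.2f+/-%.2f, stand %.2f+/-%.3f ",
                     "a.u.; stopwatch %.2f+/-%.2f s\n"),
              x$label, x$unload_mean, x$unload_sd, x$seatoff_mean,
              x$seatoff_sd, x$stab_mean, x$stab_sd, x$stand_mean,
              x$stand_sd, x$stopwatch_mean_s, x$stopwatch_sd_s))
  invisible(x)
}
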