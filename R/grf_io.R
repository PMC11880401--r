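# Reading/writing force-plate recordings and the two normalizations used in
# the analysis: body-weight normalization (Fz / m g, for quantification) and
# per-cycle peak normalization (for DTW clustering).

#' A force-plate recording with participant metadata
#'
#' @param participant_id Identifier.
#' @param sampling_rate_hz Sampling rate (> 0).
#' @param fz_raw Vertical ground reaction force in Newtons (finite,
#'   length >= 2).
#' @param mass_kg Body mass in kg (> 0).
#' @param sex Optional sex label.
#' @param stopwatch_s Optional stopwatch 5CRT duration in seconds.
#' @return An object of class `crt_recording`.
#' @export
crt_recording <- function(participant_id, sampling_rate_hz, fz_raw, mass_kg,
                          sex = NA_character_, stopwatch_s = NA_real_) {
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be positive")
  if (!is.numeric(mass_kg) || mass_kg <= 0)
    stop("mass_kg must be positive")
  if (!is.numeric(fz_raw) || length(fz_raw) < 2 || !all(is.finite(fz_raw)))
    stop("fz_raw must be a finite numeric series of length >= 2")
  structure(list(participant_id = as.character(participant_id),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 fz_raw = as.numeric(fz_raw),
                 mass_kg = as.numeric(mass_kg),
                 sex = sex,
                 stopwatch_s = as.numeric(stopwatch_s)),
            class = "crt_recording")
}

#' @export
print.crt_recording <- function(x, ...) {
  cat(sprintf(
    "5CRT recording %s: %d samples at %g Hz (%.2f s), mass %.1f kg\n",
    x$participant_id, length(x$fz_raw), x$sampling_rate_hz,
    length(x$fz_raw) / x$sampling_rate_hz, x$mass_kg))
  invisible(x)
}

#' Read a force-plate recording from CSV
#'
#' Expects a comma-separated file with a header row and columns `time_s`
#' (monotonically increasing, constant step within 1%) and `fz_n` (Newtons).
#' The sampling rate is inferred from the median time step and, when
#' `metadata` carries a `sampling_rate_hz` column, cross-checked against it.
#'
#' @param path CSV file path.
#' @param metadata Either a one-row data frame / list with at least
#'   `participant_id` and `mass_kg` (plus optional `sex`, `stopwatch_s`,
#'   `sampling_rate_hz`), or a multi-row cohort metadata data frame from
#'   which the row is joined by `participant_id`.
#' @param participant_id Required when `metadata` has several rows.
#' @return A [crt_recording()].
#' @export
read_recording <- function(path, metadata, participant_id = NULL) {
  df <- utils::read.csv(path)
  if (nrow(df) < 2) stop("recording file has fewer than 2 samples: ", path)
  if (!all(c("time_s", "fz_n") %in% names(df)))
    stop("recording CSV must contain columns time_s and fz_n")
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  step <- stats::median(dt)
  if (any(abs(dt - step) > 0.01 * step))
    stop("time_s must have a constant sampling interval (within 1%)")
  rate <- 1 / step
  md <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (nrow(md) > 1) {
    if (is.null(participant_id))
      stop("participant_id required to join multi-row metadata")
    md <- md[md$participant_id == participant_id, , drop = FALSE]
    if (nrow(md) != 1)
      stop("metadata does not identify participant ", participant_id)
  }
  if (!is.null(md$sampling_rate_hz) && is.finite(md$sampling_rate_hz) &&
      abs(md$sampling_rate_hz - rate) > 0.01 * md$sampling_rate_hz)
    stop(sprintf("inferred rate %.3f Hz disagrees with metadata (%g Hz)",
                 rate, md$sampling_rate_hz))
  crt_recording(participant_id = md$participant_id,
                sampling_rate_hz = rate,
                fz_raw = df$fz_n,
                mass_kg = md$mass_kg,
                sex = if (is.null(md$sex)) NA_character_ else md$sex,
                stopwatch_s = if (is.null(md$stopwatch_s)) NA_real_
                              else md$stopwatch_s)
}

#' Write a recording to CSV
#'
#' Emits the `time_s`, `fz_n` dialect read by [read_recording()]
#' (comma-separated, header, '.' decimal, full double precision).
#'
#' @param rec A `crt_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "crt_recording"))
  n <- length(rec$fz_raw)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$sampling_rate_hz,
                   fz_n = rec$fz_raw)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' One `<participant_id>.csv` per recording plus `cohort.csv` metadata
#' (participant_id, sex, mass_kg, stopwatch_s, archetype) and `truth.json`
#' with the landmark ground truth.
#'
#' @param cohort A `crt_cohort` from [synth_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "crt_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in cohort$recordings)
    write_recording(rec, file.path(dir, paste0(rec$participant_id, ".csv")))
  meta <- do.call(rbind, lapply(seq_along(cohort$recordings), function(i) {
    r <- cohort$recordings[[i]]
    data.frame(participant_id = r$participant_id, sex = r$sex,
               mass_kg = r$mass_kg, stopwatch_s = r$stopwatch_s,
               archetype = cohort$truth[[i]]$archetype_label)
  }))
  utils::write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Body-weight normalization
#'
#' Divides the raw vertical force by the participant's body weight,
#' `Fz = Fz_raw / (m g)`, so that quiet standing sits at 1 a.u.
#'
#' @param rec A `crt_recording`.
#' @param g Gravitational acceleration (default 9.81 m/s^2).
#' @return An object of class `crt_normalized` with `values` (a.u.), `mode =
#'   "bodyweight"` and the source span.
#' @export
normalize_bodyweight <- function(rec, g = 9.81) {
  stopifnot(inherits(rec, "crt_recording"))
  if (rec$mass_kg <= 0) stop("mass_kg must be positive")
  new_normalized(rec$fz_raw / (rec$mass_kg * g), "bodyweight",
                 c(1L, length(rec$fz_raw)))
}

#' Peak normalization
#'
#' Divides a series by its maximum so the peak is exactly 1. Applied per
#' chair-rise cycle before DTW clustering, making cycles comparable across
#' participants regardless of absolute force level. Idempotent.
#'
#' @param series Numeric series (or `crt_normalized`) with a positive
#'   maximum.
#' @param span Optional 1-based source index range, stored for provenance.
#' @return A `crt_normalized` with `mode = "peak"` and `max(values) == 1`.
#' @export
normalize_peak <- function(series, span = NULL) {
  values <- if (inherits(series, "crt_normalized")) series$values
            else as.numeric(series)
  check_series(values, "series")
  m <- max(values)
  if (m <= 0) stop("peak normalization requires a positive maximum")
  new_normalized(values / m, "peak",
                 if (is.null(span)) c(1L, length(values)) else span)
}

new_normalized <- function(values, mode, span) {
  structure(list(values = values, mode = mode, span = as.integer(span)),
            class = "crt_normalized")
}

#' @export
print.crt_normalized <- function(x, ...) {
  cat(sprintf("%s-normalized series: %d samples, range [%.3f, %.3f] a.u.\n",
              x$mode, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Integer downsampling
#'
#' Keeps every `factor`-th sample. Used to shorten cycles before the O(MN)
#' DTW computations; the stored recordings are never modified.
#'
#' @param x Numeric series.
#' @param factor Positive integer decimation factor.
#' @return The decimated series.
#' @export
downsample_series <- function(x, factor) {
  if (factor != round(factor) || factor < 1)
    stop("factor must be a positive integer")
  x[seq(1, length(x), by = factor)]
}
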