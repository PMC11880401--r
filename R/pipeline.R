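# End-to-end 5CRT analysis: segmentation, phase extraction, first-cycle DTW
# k-means, held-out assignment of cycles 2-5, and the cohort-level reports.

#' Run the full 5CRT movement-pattern analysis
#'
#' For every recording: body-weight-normalize, detect the active span, split
#' it into five chair-rise cycles, and extract the per-cycle Schenkman phase
#' forces. DTW k-means (with DBA barycenters) is then fitted on the
#' peak-normalized, downsampled first cycles; labels are canonicalized by
#' ascending mean stabilization force, the remaining cycles are assigned
#' with the fitted model, and the cohort reports (cluster summary,
#' consistency table, duration regression, SPPB scores) are assembled.
#' Recordings that do not segment into the expected number of cycles are
#' excluded and listed in `failures`.
#'
#' @param recordings A `crt_cohort` or list of `crt_recording` objects.
#' @param k Number of clusters (default 2).
#' @param n_init,max_iter Restarts and iteration cap of [dtw_kmeans()]
#'   (defaults 10 and 100).
#' @param seed Seed for the clustering restarts.
#' @param downsample Integer decimation factor applied to the cycles before
#'   DTW (default 4: 200 Hz recordings are clustered at 50 Hz).
#' @param expected_cycles Chair rises per test (default 5).
#' @return Object of class `crt_pipeline_result`: `meta` (per participant:
#'   cluster, durations, score), `phases` (per cycle phase forces),
#'   `cycle_labels` (participants x cycles), `model`, `consistency`,
#'   `summary`, `regression`, `failures`.
#' @export
run_crt_pipeline <- function(recordings, k = 2, n_init = 10, max_iter = 100,
                             seed = 1L, downsample = 4L,
                             expected_cycles = 5L) {
  if (inherits(recordings, "crt_cohort")) recordings <- recordings$recordings
  stopifnot(is.list(recordings), length(recordings) >= 1)
  per <- lapply(recordings, prepare_participant,
                downsample = downsample, expected = expected_cycles)
  failed <- vapply(per, function(p) !is.null(p$failure), TRUE)
  failures <- do.call(rbind, c(list(
    data.frame(participant_id = character(0), reason = character(0))),
    lapply(per[failed], function(p)
      data.frame(participant_id = p$participant_id, reason = p$failure))))
  per <- per[!failed]
  if (length(per) < k)
    stop("fewer successfully segmented recordings than clusters")
  first_cycles <- lapply(per, function(p) p$cycles_ds[[1]])
  phases <- do.call(rbind, lapply(per, `[[`, "phases"))
  stab1 <- vapply(per, function(p) p$phases$stab[1], 0)
  model <- dtw_kmeans(first_cycles, k = k, n_init = n_init,
                      max_iter = max_iter, seed = seed,
                      stab_values = stab1)
  n <- length(per)
  cycle_labels <- matrix(NA_integer_, n, expected_cycles)
  cycle_labels[, 1] <- model$labels
  for (cyc in seq_len(expected_cycles)[-1]) {
    cycs <- lapply(per, function(p) p$cycles_ds[[cyc]])
    cycle_labels[, cyc] <- assign_series(model, cycs)
  }
  meta <- data.frame(
    participant_id = vapply(per, `[[`, "", "participant_id"),
    cluster = model$labels,
    sex = vapply(per, function(p) as.character(p$sex), ""),
    mass_kg = vapply(per, function(p) p$mass_kg, 0),
    stopwatch_s = vapply(per, function(p) p$stopwatch_s, 0),
    t_grf_s = vapply(per, function(p) p$t_grf_s, 0))
  meta$score <- guralnik_score(ifelse(is.na(meta$stopwatch_s),
                                      meta$t_grf_s, meta$stopwatch_s))
  phase1 <- phases[phases$cycle == 1,
                   c("participant_id", "unload", "seatoff", "stab", "stand")]
  summary_rep <- cohort_summary(meta, phase1)
  consistency <- if (expected_cycles == 5) consistency_table(cycle_labels)
  regression <- if (all(is.finite(meta$stopwatch_s)))
    duration_regression(meta$stopwatch_s, meta$t_grf_s)
  structure(list(meta = meta, phases = phases,
                 cycle_labels = cycle_labels, model = model,
                 consistency = consistency, summary = summary_rep,
                 regression = regression, failures = failures),
            class = "crt_pipeline_result")
}

# Segment one recording and precompute everything the pipeline needs.
prepare_participant <- function(rec, downsample, expected) {
  stopifnot(inherits(rec, "crt_recording"))
  out <- list(participant_id = rec$participant_id, sex = rec$sex,
              mass_kg = rec$mass_kg, stopwatch_s = rec$stopwatch_s)
  seg <- tryCatch(segment_recording(rec, expected = expected),
                  error = function(e) e)
  if (inherits(seg, "error")) {
    out$failure <- conditionMessage(seg)
    return(out)
  }
  bw <- normalize_bodyweight(rec)$values
  cycles_raw <- lapply(seq_len(nrow(seg$cycles)), function(kk)
    bw[seg$cycles$start_idx[kk]:(seg$cycles$end_idx[kk] - 1L)])
  ph <- tryCatch(phase_report(rec, seg), error = function(e) e)
  if (inherits(ph, "error") || any(is.na(ph$stab))) {
    out$failure <- if (inherits(ph, "error")) conditionMessage(ph)
                   else "phase detection failed on at least one cycle"
    return(out)
  }
  out$segmentation <- seg
  out$t_grf_s <- grf_duration(seg)
  out$phases <- ph
  out$cycles_ds <- lapply(cycles_raw, function(cc)
    normalize_peak(downsample_series(cc, downsample))$values)
  out
}

#' Write a pipeline result to a report directory
#'
#' Emits the machine-readable artifacts of [run_crt_pipeline()]:
#' `labels.csv` (participant_id, cycle, label), `phases.csv` (per-cycle
#' phase forces), `meta.csv` (per-participant cluster, durations, score),
#' `summary.json` (cluster sizes, duration and phase comparisons,
#' consistency table), `regression.json`, `failures.csv`, and one
#' `barycenter_<k>.csv` per cluster centroid.
#'
#' @param result A `crt_pipeline_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(result, dir) {
  stopifnot(inherits(result, "crt_pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  labels <- data.frame(
    participant_id = rep(result$meta$participant_id,
                         ncol(result$cycle_labels)),
    cycle = rep(seq_len(ncol(result$cycle_labels)),
                each = nrow(result$cycle_labels)),
    label = as.vector(result$cycle_labels))
  utils::write.csv(labels[order(labels$participant_id, labels$cycle), ],
                   file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(result$phases, file.path(dir, "phases.csv"),
                   row.names = FALSE)
  utils::write.csv(result$meta, file.path(dir, "meta.csv"),
                   row.names = FALSE)
  utils::write.csv(result$failures, file.path(dir, "failures.csv"),
                   row.names = FALSE)
  s <- result$summary
  jsonlite::write_json(list(
    cluster_sizes = as.list(stats::setNames(as.integer(s$cluster_sizes),
                                            names(s$cluster_sizes))),
    durations = s$durations,
    duration_comparison = s$duration_comparison,
    phase_comparison = s$phase_comparison,
    consistency = result$consistency),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  if (!is.null(result$regression))
    jsonlite::write_json(result$regression[c("slope", "intercept_s",
                                             "slope_se", "intercept_se",
                                             "n")],
                         file.path(dir, "regression.json"),
                         auto_unbox = TRUE, digits = NA)
  for (j in seq_along(result$model$barycenters))
    utils::write.csv(data.frame(value = result$model$barycenters[[j]]),
                     file.path(dir, sprintf("barycenter_%d.csv", j)),
                     row.names = FALSE)
  invisible(dir)
}

#' @export
print.crt_pipeline_result <- function(x, ...) {
  cat(sprintf("5CRT pipeline: %d participants analysed, %d excluded\n",
              nrow(x$meta), nrow(x$failures)))
  print(x$summary)
  if (!is.null(x$regression)) print(x$regression)
  invisible(x)
}
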