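# Scoring, hypothesis tests, regression and the cluster summary /
# consistency reports.

#' SPPB chair-rise score (Guralnik bands)
#'
#' Maps a measured 5CRT duration onto the 0-4 point SPPB chair-rise score:
#' <= 11.19 s scores 4, 11.20-13.69 s scores 3, 13.70-16.69 s scores 2,
#' 16.70-60 s scores 1, and > 60 s (or an incomplete test) scores 0.
#' Durations are rounded half-up to two decimals before banding, matching
#' the printed band precision, so the bands tile (0, Inf) without gaps.
#'
#' @param duration_s 5CRT duration in seconds (vectorized), or `NA` with
#'   `unable = TRUE`.
#' @param unable Logical (recycled): participant could not complete the test.
#' @return Integer score(s) 0-4.
#' @examples
#' guralnik_score(c(11.19, 12, 61))
#' @export
guralnik_score <- function(duration_s, unable = FALSE) {
  unable <- rep_len(unable, length(duration_s))
  if (any(!unable & (is.na(duration_s) | duration_s <= 0)))
    stop("duration_s must be positive unless unable = TRUE")
  d <- floor(duration_s * 100 + 0.5) / 100   # round half-up, 2 decimals
  score <- ifelse(d <= 11.19, 4L,
           ifelse(d <= 13.69, 3L,
           ifelse(d <= 16.69, 2L,
           ifelse(d <= 60.00, 1L, 0L))))
  score[unable] <- 0L
  as.integer(score)
}

#' Compare per-cluster variable distributions
#'
#' For each variable, reports per-cluster means and SDs, Shapiro-Wilk
#' normality p-values per group (the audit trail motivating a non-parametric
#' comparison), and the two-sided Mann-Whitney U p-value between the two
#' groups. The Mann-Whitney test is always used regardless of the
#' Shapiro-Wilk outcome; significance is flagged at `alpha`.
#'
#' @param values Named list of numeric vectors (one per variable), each
#'   observation paired with `labels`; or a data frame of variables.
#' @param labels Cluster labels (exactly 2 groups, >= 3 values each).
#' @param alpha Significance level (default 0.01).
#' @return Data frame with one row per variable: group means/SDs,
#'   Shapiro-Wilk p per group, Mann-Whitney `p_value` and `significant`.
#' @export
compare_clusters <- function(values, labels, alpha = 0.01) {
  if (is.data.frame(values)) values <- as.list(values)
  if (!is.list(values)) values <- list(value = values)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("compare_clusters expects exactly 2 groups")
  g <- levels(labels)
  rows <- lapply(names(values), function(nm) {
    x <- values[[nm]]
    ok <- !is.na(x)
    x1 <- x[ok & labels == g[1]]
    x2 <- x[ok & labels == g[2]]
    if (length(x1) < 3 || length(x2) < 3)
      stop("each group needs >= 3 values for variable ", nm)
    degenerate <- stats::sd(x1) == 0 || stats::sd(x2) == 0
    sw <- function(v) {
      if (stats::sd(v) == 0 || length(v) < 3 || length(v) > 5000)
        return(NA_real_)
      stats::shapiro.test(v)$p.value
    }
    p <- suppressWarnings(
      stats::wilcox.test(x1, x2, alternative = "two.sided")$p.value)
    data.frame(variable = nm,
               mean_1 = mean(x1), sd_1 = stats::sd(x1),
               mean_2 = mean(x2), sd_2 = stats::sd(x2),
               shapiro_p_1 = sw(x1), shapiro_p_2 = sw(x2),
               p_value = p,
               significant = p < alpha,
               degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}

#' Regression of GRF-labeled duration on stopwatch duration
#'
#' Ordinary least squares of `t_GRF` on `t_stopwatch`, quantifying the
#' systematic offset between the force-plate-labeled and the manually timed
#' 5CRT duration.
#'
#' @param t_stopwatch,t_grf Paired durations in seconds (>= 3 pairs,
#'   non-constant predictor).
#' @return Object of class `crt_duration_regression`: `slope`, `intercept_s`,
#'   their standard errors, `residuals`, and the underlying `lm` fit.
#' @export
duration_regression <- function(t_stopwatch, t_grf) {
  ok <- is.finite(t_stopwatch) & is.finite(t_grf)
  t_stopwatch <- t_stopwatch[ok]; t_grf <- t_grf[ok]
  if (length(t_grf) < 3) stop("need at least 3 duration pairs")
  if (stats::sd(t_stopwatch) == 0) stop("constant predictor")
  fit <- stats::lm(t_grf ~ t_stopwatch)
  cf <- summary(fit)$coefficients
  structure(list(slope = unname(cf["t_stopwatch", "Estimate"]),
                 intercept_s = unname(cf["(Intercept)", "Estimate"]),
                 slope_se = unname(cf["t_stopwatch", "Std. Error"]),
                 intercept_se = unname(cf["(Intercept)", "Std. Error"]),
                 residuals = unname(stats::residuals(fit)),
                 n = length(t_grf),
                 fit = fit),
            class = "crt_duration_regression")
}

#' @export
print.crt_duration_regression <- function(x, ...) {
  cat(sprintf("t_GRF = %.3f * t_stopwatch + %.3f  (n = %d, SE %.3f / %.3f)\n",
              x$slope, x$intercept_s, x$n, x$slope_se, x$intercept_se))
  invisible(x)
}

#' Cluster-consistency table
#'
#' For participants labeled on every chair rise, tabulates -- per
#' first-cycle cluster and in total -- the fraction whose first-cycle label
#' is shared by all five, four, three, or two of their rises, and the
#' "only first" category (cycles 2-5 all in the other cluster).
#'
#' @param labels Integer matrix or data frame, one row per participant and
#'   one column per cycle (5 columns); no missing values.
#' @return Data frame with rows per first-cycle cluster plus `total`, columns
#'   `n`, `all`, `four`, `three`, `two`, `only_first` (fractions summing to 1
#'   per row).
#' @export
consistency_table <- function(labels) {
  m <- as.matrix(labels)
  if (ncol(m) != 5) stop("need 5 cycle labels per participant")
  if (any(is.na(m))) stop("missing cycle labels")
  first <- m[, 1]
  matches <- rowSums(m == first)     # includes the first cycle, so 1..5
  cat_of <- c("only_first", "two", "three", "four", "all")[matches]
  cats <- c("all", "four", "three", "two", "only_first")
  mk_row <- function(sel, name) {
    n <- sum(sel)
    fr <- vapply(cats, function(cc) mean(cat_of[sel] == cc), 0)
    cbind(data.frame(cluster = name, n = n), as.data.frame(as.list(fr)))
  }
  rows <- lapply(sort(unique(first)), function(cl)
    mk_row(first == cl, as.character(cl)))
  out <- rbind(do.call(rbind, rows), mk_row(rep(TRUE, nrow(m)), "total"))
  rownames(out) <- NULL
  out
}

#' Cohort summary report
#'
#' Assembles the cohort-level results: per-cluster sizes and sex split,
#' stopwatch and GRF duration means +/- SD, SPPB chair-rise score
#' distribution, per-phase force means +/- SD with Mann-Whitney p-values
#' (when exactly two clusters are present), and overall covariate ranges.
#'
#' @param meta Data frame with one row per participant: `participant_id`,
#'   `cluster` (first-cycle label), optional `sex`, `mass_kg`,
#'   `stopwatch_s`, `t_grf_s`.
#' @param phase Data frame of first-cycle phase forces per participant:
#'   `participant_id`, `unload`, `seatoff`, `stab`, `stand`.
#' @param alpha Significance level for the cluster comparisons.
#' @return Object of class `crt_cohort_summary`: list with `cluster_sizes`,
#'   `durations` (per-cluster mean/SD), `phase_comparison`
#'   (see [compare_clusters()]), `scores`, `population`.
#' @export
cohort_summary <- function(meta, phase, alpha = 0.01) {
  stopifnot(is.data.frame(meta), "cluster" %in% names(meta))
  df <- merge(meta, phase, by = "participant_id", sort = TRUE)
  single <- nrow(df) < 2
  msd <- function(x) c(mean = mean(x, na.rm = TRUE),
                       sd = if (sum(is.finite(x)) < 2) 0
                            else stats::sd(x, na.rm = TRUE))
  cl <- sort(unique(df$cluster))
  durations <- do.call(rbind, lapply(cl, function(g) {
    s <- df[df$cluster == g, ]
    data.frame(cluster = g, n = nrow(s),
               stopwatch_mean = msd(s$stopwatch_s)[1],
               stopwatch_sd = msd(s$stopwatch_s)[2],
               t_grf_mean = msd(s$t_grf_s)[1],
               t_grf_sd = msd(s$t_grf_s)[2])
  }))
  phase_comparison <- NULL
  duration_p <- NULL
  if (length(cl) == 2 && min(table(df$cluster)) >= 3) {
    phase_comparison <- compare_clusters(
      df[, c("unload", "seatoff", "stab", "stand")], df$cluster, alpha)
    duration_p <- compare_clusters(
      list(stopwatch_s = df$stopwatch_s, t_grf_s = df$t_grf_s),
      df$cluster, alpha)
  }
  scores <- if (!is.null(df$stopwatch_s))
    table(cluster = df$cluster, score = guralnik_score(df$stopwatch_s))
  population <- list(n = nrow(df),
                     sex = if (!is.null(df$sex)) table(df$sex),
                     mass_kg = if (!is.null(df$mass_kg)) msd(df$mass_kg),
                     single_participant = single)
  structure(list(cluster_sizes = table(df$cluster),
                 durations = durations,
                 duration_comparison = duration_p,
                 phase_comparison = phase_comparison,
                 scores = scores,
                 population = population),
            class = "crt_cohort_summary")
}

#' @export
print.crt_cohort_summary <- function(x, ...) {
  cat("5CRT cohort summary\n")
  cat("cluster sizes: ",
      paste(sprintf("%s: %d", names(x$cluster_sizes), x$cluster_sizes),
            collapse = ", "), "\n", sep = "")
  print(x$durations, row.names = FALSE)
  if (!is.null(x$phase_comparison)) {
    cat("phase-force comparison:\n")
    print(x$phase_comparison[, c("variable", "mean_1", "sd_1", "mean_2",
                                 "sd_2", "p_value", "significant")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
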