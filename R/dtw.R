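#' Pairwise cross-similarity matrix
#'
#' Computes the M x N matrix of inner alignment costs between two series,
#' entry (i, j) holding the squared difference `(x_i - y_j)^2`. This is the
#' local-cost matrix over which the dynamic-programming alignment of
#' [dtw_distance()] optimizes.
#'
#' @param x,y Numeric series (finite, non-empty).
#' @return A `length(x)` x `length(y)` numeric matrix.
#' @examples
#' cross_similarity(c(0, 1), c(3, 1))
#' @export
cross_similarity <- function(x, y) {
  check_series(x, "x")
  check_series(y, "y")
  outer(x, y, function(a, b) (a - b)^2)
}

#' Dynamic time warping distance with path recovery
#'
#' Exact dynamic programming over all admissible warp paths (steps down, right
#' and diagonal; endpoints pinned to the first and last samples of both
#' series). The inner cost is the squared difference and one square root is
#' taken of the accumulated optimum, so `dtw_distance(x, y)$distance` equals
#' `sqrt(min over paths of sum (x_i - y_j)^2)`. Series may differ in length;
#' no interpolation is performed. Ties during backtracking are broken in the
#' fixed order diagonal, vertical, horizontal, making the recovered path
#' deterministic.
#'
#' @param x,y Numeric series (finite, non-empty; lengths may differ).
#' @param keep_matrix Keep the accumulated cost matrix in the result?
#' @return An object of class `crt_dtw`: a list with `distance` (non-negative
#'   scalar), `path` (K x 2 integer matrix of 1-based index pairs into `x` and
#'   `y`) and, if requested, `acc` (the accumulated cost matrix).
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 3))$distance  # 1
#' @export
dtw_distance <- function(x, y, keep_matrix = FALSE) {
  check_series(x, "x")
  check_series(y, "y")
  res <- dtw_path_cpp(as.numeric(x), as.numeric(y))
  out <- list(distance = sqrt(res$cost), path = res$path)
  if (keep_matrix) {
    M <- length(x); N <- length(y)
    acc <- matrix(NA_real_, M, N)
    # rebuild by re-running the DP in R space is wasteful; derive from costs
    D <- matrix(Inf, M + 1, N + 1); D[1, 1] <- 0
    cs <- cross_similarity(x, y)
    for (i in seq_len(M)) for (j in seq_len(N))
      D[i + 1, j + 1] <- cs[i, j] + min(D[i, j], D[i, j + 1], D[i + 1, j])
    out$acc <- D[-1, -1, drop = FALSE]
  }
  class(out) <- "crt_dtw"
  out
}

#' @export
print.crt_dtw <- function(x, ...) {
  cat(sprintf("DTW alignment: distance %.6g, path length %d\n",
              x$distance, nrow(x$path)))
  invisible(x)
}

#' Pairwise DTW distance matrix
#'
#' @param series List of numeric series.
#' @return Symmetric matrix of DTW distances (square-rooted accumulated
#'   optima), zero diagonal.
#' @export
dtw_pairwise <- function(series) {
  stopifnot(is.list(series), length(series) >= 1)
  lapply(series, check_series, name = "series")
  dtw_pairwise_cpp(lapply(series, as.numeric))
}

#' DTW Barycenter Averaging (DBA)
#'
#' Iteratively refines a barycenter of a set of series under the DTW metric:
#' each series is aligned to the current barycenter along its optimal warp
#' path, and every barycenter coordinate is replaced by the mean of all sample
#' values aligned onto it. The objective that this update provably does not
#' increase is the within-set sum of squared DTW distances,
#' `sum_x DTW(mu, x)^2`, and that is the objective reported and used for the
#' stopping rule (relative improvement below `tol`, or `max_iter`).
#'
#' When `init` is `NULL` the barycenter is initialized at the DTW medoid of
#' the set (the member with the smallest summed distance to all others),
#' which is deterministic given the data; its length is then the set's median
#' series length (the medoid is resampled linearly if needed).
#'
#' @param series List of numeric series.
#' @param init Optional initial barycenter (numeric series).
#' @param max_iter Maximum DBA iterations (default 30).
#' @param tol Relative objective improvement below which iteration stops.
#' @return List with `barycenter`, `objective` (final sum of squared DTW
#'   distances), and `objective_trace` (one value per evaluated iterate,
#'   starting from the initializer).
#' @examples
#' dba_barycenter(list(c(2, 2, 2), c(4, 4, 4)), init = c(3, 3, 3))$barycenter
#' @export
dba_barycenter <- function(series, init = NULL, max_iter = 30, tol = 1e-6) {
  stopifnot(is.list(series))
  if (length(series) == 0) stop("DBA requires a non-empty set of series")
  lapply(series, check_series, name = "series")
  series <- lapply(series, as.numeric)
  if (is.null(init)) {
    med_len <- stats::median(lengths(series))
    dm <- dtw_pairwise_cpp(series)
    medoid <- series[[which.min(rowSums(dm))]]
    init <- resample_linear(medoid, round(med_len))
  }
  mu <- as.numeric(init)
  trace <- numeric(0)
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    upd <- dba_update_cpp(series, mu)
    obj <- upd$objective          # objective at the incoming mu
    trace <- c(trace, obj)
    if (is.finite(obj_prev) &&
        (obj_prev - obj) < tol * max(obj_prev, .Machine$double.eps)) {
      break
    }
    obj_prev <- obj
    mu <- upd$mu
  }
  final_obj <- sum(vapply(series, function(x) dtw_cost_cpp(mu, x), 0))
  list(barycenter = mu, objective = final_obj,
       objective_trace = c(trace, final_obj))
}

#' Soft-DTW cost
#'
#' Smoothed DTW in which the hard minimum of the dynamic program is replaced
#' by `softmin_gamma(a) = -gamma * log(sum_i exp(-a_i / gamma))`. As
#' `gamma -> 0` the soft cost converges to the squared DTW cost (the
#' accumulated optimum before the square root).
#'
#' @param x,y Numeric series.
#' @param gamma Smoothing parameter, strictly positive.
#' @return Scalar soft-DTW cost (may be negative for small structure and
#'   large `gamma`).
#' @export
softdtw_distance <- function(x, y, gamma = 1.0) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a positive scalar")
  check_series(x, "x")
  check_series(y, "y")
  softdtw_cpp(as.numeric(x), as.numeric(y), gamma)
}

#' Soft-DTW barycenter
#'
#' Minimizes `sum_x softDTW_gamma(mu, x)` over the barycenter `mu` by
#' quasi-Newton descent (`stats::optim`, L-BFGS-B) using the analytic
#' soft-alignment gradient. Used to render smooth cluster-representative
#' waveforms; the hard-min DBA barycenter of [dba_barycenter()] remains the
#' clustering workhorse.
#'
#' @param series List of numeric series.
#' @param gamma Smoothing parameter, strictly positive (default 1).
#' @param max_iter Optimizer iteration cap.
#' @param init Optional initial barycenter; defaults to the linearly
#'   resampled element-wise mean at the median series length.
#' @return List with `barycenter` and `objective`.
#' @export
softdtw_barycenter <- function(series, gamma = 1.0, max_iter = 100,
                               init = NULL) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a positive scalar")
  stopifnot(is.list(series), length(series) >= 1)
  series <- lapply(series, as.numeric)
  lapply(series, check_series, name = "series")
  if (is.null(init)) {
    L <- round(stats::median(lengths(series)))
    init <- rowMeans(vapply(series, resample_linear, numeric(L), n_out = L))
  }
  fn <- function(z) sum(vapply(series, function(x)
    softdtw_cpp(z, x, gamma), 0))
  gr <- function(z) {
    g <- numeric(length(z))
    for (x in series) g <- g + softdtw_grad_cpp(z, x, gamma)$grad
    g
  }
  fit <- stats::optim(as.numeric(init), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter))
  list(barycenter = fit$par, objective = fit$value)
}

# Linear resampling of a series to n_out samples (index-proportional).
resample_linear <- function(x, n_out) {
  if (length(x) == n_out) return(as.numeric(x))
  stats::approx(seq_along(x), x, n = n_out)$y
}

# Shared argument validation for series inputs.
check_series <- function(x, name = "series") {
  if (!is.numeric(x) || length(x) == 0)
    stop(sprintf("%s must be a non-empty numeric series", name))
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite values", name))
  invisible(TRUE)
}
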