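# DTW-metric k-means over chair-rise cycles (Lloyd iterations with DBA
# barycenter updates), held-out assignment, and internal cluster validation.

#' DTW k-means with DBA barycenter updates
#'
#' Lloyd-style alternation under the DTW metric: every series is assigned to
#' its nearest barycenter by DTW distance and each barycenter is recomputed
#' by DTW Barycenter Averaging over its members (warm-started from the
#' current barycenter). Iteration stops on label stability or `max_iter`.
#' The whole procedure is restarted `n_init` times from different centroid
#' draws (k distinct series sampled without replacement per restart
#' substream) and the restart with the smallest inertia (sum of squared DTW
#' distances to the assigned barycenter) is returned. Empty clusters are
#' reseeded with the series farthest from its barycenter, so no fewer than
#' `k` non-empty clusters are returned when the data contain `k` distinct
#' series.
#'
#' Cluster labels are canonicalized after fitting: clusters are renumbered by
#' ascending stabilization-phase force (the supplied `stab_values` member
#' means, or, failing that, the post-peak minimum of each barycenter), so
#' cluster 1 always denotes the low-stabilization-force movement pattern.
#'
#' @param series List of numeric series (typically peak-normalized first
#'   chair-rise cycles).
#' @param k Number of clusters (>= 1).
#' @param n_init Number of seeded restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @param seed Integer seed driving all restarts.
#' @param dba_iter DBA refinement iterations per barycenter update.
#' @param stab_values Optional numeric vector (one per series) of
#'   stabilization-phase forces used for label canonicalization.
#' @return Object of class `crt_kmeans`: `k`, `barycenters`, `labels`
#'   (training labels), `inertia`, `inertia_trace` (per Lloyd iteration of
#'   the winning restart), `n_init`, `max_iter`, `seed`.
#' @export
dtw_kmeans <- function(series, k, n_init = 10, max_iter = 100, seed = 1L,
                       dba_iter = 10, stab_values = NULL) {
  stopifnot(is.list(series))
  n <- length(series)
  if (k < 1) stop("k must be >= 1")
  if (n < k) stop("dataset smaller than k")
  series <- lapply(series, as.numeric)
  lapply(series, check_series, name = "series")
  if (n_distinct_series(series) < k && k > 1)
    warning("fewer distinct series than clusters; clusters will degenerate")
  set.seed(as.integer(seed))
  restart_seeds <- sample.int(.Machine$integer.max - 1L, n_init)
  best <- NULL
  for (r in seq_len(n_init)) {
    set.seed(restart_seeds[r])
    centers <- series[sample.int(n, k)]
    labels_prev <- rep(0L, n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      D <- dtw_to_refs_cpp(series, centers)
      labels <- max.col(-D, ties.method = "first")
      dmin <- D[cbind(seq_len(n), labels)]
      for (j in seq_len(k)) {
        if (!any(labels == j)) {
          far <- order(dmin, decreasing = TRUE)
          far <- far[tabulate(labels, k)[labels[far]] >= 2]
          if (length(far) == 0) break
          labels[far[1]] <- j
          dmin[far[1]] <- 0
        }
      }
      trace <- c(trace, sum(dmin^2))
      it_n <- length(trace)
      # stop on label stability, or when the objective has plateaued
      # (oscillating boundary assignments no longer improve the fit)
      if (identical(labels, labels_prev)) break
      if (it_n > 2 &&
          abs(trace[it_n - 1] - trace[it_n]) <
            1e-6 * max(trace[it_n - 1], .Machine$double.eps)) break
      labels_prev <- labels
      centers <- lapply(seq_len(k), function(j)
        dba_barycenter(series[labels == j], init = centers[[j]],
                       max_iter = dba_iter)$barycenter)
    }
    D <- dtw_to_refs_cpp(series, centers)
    labels <- max.col(-D, ties.method = "first")
    inertia <- sum(D[cbind(seq_len(n), labels)]^2)
    if (is.null(best) || inertia < best$inertia)
      best <- list(centers = centers, labels = labels, inertia = inertia,
                   trace = trace)
  }
  model <- structure(list(k = as.integer(k),
                          barycenters = best$centers,
                          labels = best$labels,
                          inertia = best$inertia,
                          inertia_trace = best$trace,
                          n_init = n_init, max_iter = max_iter,
                          seed = as.integer(seed)),
                     class = "crt_kmeans")
  canonicalize_clusters(model, stab_values)
}

n_distinct_series <- function(series) {
  length(unique(vapply(series, function(x)
    paste(signif(x, 12), collapse = ","), "")))
}

# Renumber clusters by ascending stabilization force so that cluster 1 is
# always the low-stabilization-force pattern.
canonicalize_clusters <- function(model, stab_values = NULL) {
  k <- model$k
  if (k == 1) return(model)
  key <- if (!is.null(stab_values)) {
    vapply(seq_len(k), function(j)
      mean(stab_values[model$labels == j], na.rm = TRUE), 0)
  } else {
    vapply(model$barycenters, function(b) {
      p <- which.max(b)
      if (p >= length(b)) b[length(b)] else min(b[(p + 1):length(b)])
    }, 0)
  }
  ord <- order(key)
  model$barycenters <- model$barycenters[ord]
  model$labels <- match(model$labels, ord)
  model$canonical_key <- key[ord]
  model
}

#' @export
print.crt_kmeans <- function(x, ...) {
  cat(sprintf(
    "DTW k-means: k = %d, n = %d series, inertia %.4g (%d restarts)\n",
    x$k, length(x$labels), x$inertia, x$n_init))
  cat(sprintf("cluster sizes: %s\n",
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Assign series to the nearest barycenter of a fitted model
#'
#' Deterministic: ties go to the lowest cluster label.
#'
#' @param model A fitted `crt_kmeans`.
#' @param series A numeric series or a list of them.
#' @return Integer label(s).
#' @export
assign_series <- function(model, series) {
  if (!inherits(model, "crt_kmeans") || is.null(model$barycenters))
    stop("model must be a fitted crt_kmeans")
  if (!is.list(series)) series <- list(series)
  series <- lapply(series, as.numeric)
  lapply(series, check_series, name = "series")
  D <- dtw_to_refs_cpp(series, model$barycenters)
  max.col(-D, ties.method = "first")
}

#' @export
predict.crt_kmeans <- function(object, newdata, ...) {
  assign_series(object, newdata)
}

#' Mean silhouette across candidate cluster counts
#'
#' Fits DTW k-means for every k in `k_range` and scores each clustering by
#' the mean silhouette width computed from the full pairwise DTW distance
#' matrix (cohesion versus separation of every series, averaged). The k with
#' the largest mean silhouette is the supported cluster count.
#'
#' @param series List of numeric series.
#' @param k_range Candidate cluster counts (default 2:10).
#' @param seed Seed forwarded to each fit.
#' @param n_init,max_iter Forwarded to [dtw_kmeans()].
#' @param dist_matrix Optional precomputed pairwise DTW matrix.
#' @return Object of class `crt_silhouette_sweep`: list with
#'   `silhouette_by_k` (named numeric), `best_k`, `labels_by_k` and the
#'   distance matrix.
#' @export
silhouette_sweep <- function(series, k_range = 2:10, seed = 1L, n_init = 10,
                             max_iter = 100, dist_matrix = NULL) {
  n <- length(series)
  k_range <- k_range[k_range >= 2]
  if (any(k_range > n)) {
    warning("skipping k values exceeding the dataset size")
    k_range <- k_range[k_range <= n]
  }
  if (length(k_range) == 0) stop("no admissible k in k_range")
  if (is.null(dist_matrix)) dist_matrix <- dtw_pairwise(series)
  sil <- stats::setNames(numeric(length(k_range)), k_range)
  labels_by_k <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- dtw_kmeans(series, k, n_init = n_init, max_iter = max_iter,
                      seed = seed)
    sw <- cluster::silhouette(fit$labels, dmatrix = dist_matrix)
    sil[i] <- mean(sw[, "sil_width"])
    labels_by_k[[as.character(k)]] <- fit$labels
  }
  structure(list(silhouette_by_k = sil,
                 best_k = as.integer(names(sil)[which.max(sil)]),
                 labels_by_k = labels_by_k,
                 dist_matrix = dist_matrix),
            class = "crt_silhouette_sweep")
}

#' @export
print.crt_silhouette_sweep <- function(x, ...) {
  cat("Silhouette by k:\n")
  print(round(x$silhouette_by_k, 3))
  cat(sprintf("best k = %d\n", x$best_k))
  invisible(x)
}

#' Davies-Bouldin index
#'
#' `DB = (1/k) * sum_i max_{j != i} (S_i + S_j) / M_ij`, with `S_i` the mean
#' distance of cluster i members to their barycenter and `M_ij` the distance
#' between barycenters. Lower values indicate compact, well-separated
#' clusters. The distance is DTW by default; `metric = "euclidean"` (equal
#' series lengths required) matches the classical index on multivariate
#' points and is used for cross-checking.
#'
#' @param series List of numeric series.
#' @param labels Integer cluster labels (>= 2 non-empty clusters).
#' @param centers List of cluster centers (barycenters for DTW, element-wise
#'   centroids for Euclidean).
#' @param metric `"dtw"` or `"euclidean"`.
#' @return The index value (non-negative scalar).
#' @export
davies_bouldin <- function(series, labels, centers,
                           metric = c("dtw", "euclidean")) {
  metric <- match.arg(metric)
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2) stop("Davies-Bouldin requires at least 2 non-empty clusters")
  if (length(centers) < max(ks)) stop("one center per cluster required")
  if (any(tabulate(labels) [ks] < 1)) stop("empty cluster")
  dfun <- if (metric == "dtw") {
    function(x, y) sqrt(dtw_cost_cpp(as.numeric(x), as.numeric(y)))
  } else {
    function(x, y) {
      if (length(x) != length(y))
        stop("euclidean metric requires equal series lengths")
      sqrt(sum((x - y)^2))
    }
  }
  S <- vapply(ks, function(j)
    mean(vapply(series[labels == j], dfun, 0, y = centers[[j]])), 0)
  M <- outer(seq_len(k), seq_len(k), Vectorize(function(a, b)
    if (a == b) NA_real_ else dfun(centers[[ks[a]]], centers[[ks[b]]])))
  R <- outer(S, S, "+") / M
  mean(apply(R, 1, max, na.rm = TRUE))
}
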