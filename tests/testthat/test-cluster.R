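test_that("well-separated groups are recovered perfectly", {
  tg <- two_group_series()
  fit <- dtw_kmeans(tg$series, k = 2, n_init = 4, seed = 3)
  # labels must be a relabeling of the truth with zero disagreement
  tab <- table(fit$labels, tg$truth)
  expect_equal(sort(as.vector(tab)), c(0, 0, 10, 10))
})

test_that("k = 1 returns a single barycenter whose inertia is its own objective", {
  tg <- two_group_series(n_per = 4)
  fit <- dtw_kmeans(tg$series, k = 1, n_init = 2, seed = 5)
  expect_length(fit$barycenters, 1)
  d <- vapply(tg$series, function(x)
    dtw_distance(x, fit$barycenters[[1]])$distance, 0)
  expect_equal(fit$inertia, sum(d^2))
  ref <- dba_barycenter(tg$series)
  expect_lte(fit$inertia, ref$objective * (1 + 1e-6) + 1e-9)
})

test_that("inertia never increases across Lloyd iterations and fits are reproducible", {
  tg <- two_group_series(n_per = 6, sd = 1.5, seed = 8)
  f1 <- dtw_kmeans(tg$series, 2, n_init = 3, seed = 11)
  f2 <- dtw_kmeans(tg$series, 2, n_init = 3, seed = 11)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$inertia, f2$inertia)
  expect_true(all(diff(f1$inertia_trace) <= 1e-8))
})

test_that("assignment maps each barycenter to its own cluster and is edge-stable", {
  tg <- two_group_series(n_per = 5, seed = 4)
  fit <- dtw_kmeans(tg$series, 2, n_init = 3, seed = 2)
  for (j in 1:2)
    expect_equal(assign_series(fit, fit$barycenters[[j]]), j)
  # appending one duplicated terminal sample is absorbed by the warping
  labs <- assign_series(fit, tg$series)
  padded <- lapply(tg$series, function(x) c(x, x[length(x)]))
  expect_equal(assign_series(fit, padded), labs)
  expect_error(assign_series(structure(list(), class = "crt_kmeans"), 1:3),
               "fitted")
})

test_that("degenerate requests fail or warn as promised", {
  tg <- two_group_series(n_per = 2)
  expect_error(dtw_kmeans(tg$series, k = 5), "smaller than k")
  same <- lapply(1:4, function(i) c(1, 2, 3))
  expect_warning(dtw_kmeans(same, 2, n_init = 1, seed = 1), "distinct")
})

test_that("empty-cluster repair keeps k non-empty clusters on distinct data", {
  set.seed(6)
  s <- lapply(1:8, function(i) rnorm(12, mean = i %% 2 * 5))
  fit <- dtw_kmeans(s, k = 4, n_init = 5, seed = 9)
  expect_equal(sort(unique(fit$labels)), 1:4)
  expect_true(all(tabulate(fit$labels, 4) >= 1))
})

test_that("cluster labels are canonicalized by ascending stabilization force", {
  tg <- two_group_series(seed = 14)
  stab <- ifelse(tg$truth == 1, 0.7, 0.4)  # group 2 has the LOW stab force
  fit <- dtw_kmeans(tg$series, 2, n_init = 3, seed = 1, stab_values = stab)
  expect_lt(mean(stab[fit$labels == 1]), mean(stab[fit$labels == 2]))
})

test_that("silhouette separates structure from an unstructured blob", {
  tg <- two_group_series(n_per = 8, seed = 21)
  sw <- silhouette_sweep(tg$series, k_range = 2:4, seed = 2, n_init = 3)
  expect_gt(sw$silhouette_by_k[["2"]], 0.9)
  expect_equal(sw$best_k, 2L)
  set.seed(22)
  blob <- lapply(1:16, function(i) rnorm(15))
  swb <- silhouette_sweep(blob, k_range = 2, seed = 2, n_init = 3)
  expect_lt(abs(swb$silhouette_by_k[["2"]]), 0.25)
  expect_warning(silhouette_sweep(blob, k_range = c(2, 40), seed = 1,
                                  n_init = 2), "skipping")
})

test_that("Davies-Bouldin is small for tight far clusters and grows as they merge", {
  db_at_gap <- function(gap, seed = 30) {
    set.seed(seed)
    s <- c(lapply(1:8, function(i) rnorm(12, 0, 0.2)),
           lapply(1:8, function(i) rnorm(12, gap, 0.2)))
    labels <- rep(1:2, each = 8)
    centers <- list(rep(0, 12), rep(gap, 12))
    davies_bouldin(s, labels, centers, metric = "dtw")
  }
  dbs <- vapply(c(8, 4, 2, 1), db_at_gap, 0)
  expect_lt(dbs[1], 0.2)
  expect_true(all(diff(dbs) > 0))
  expect_error(davies_bouldin(list(1:3, 1:3), c(1, 1), list(1:3)), "2 non-empty")
})

test_that("Euclidean Davies-Bouldin matches the scikit-learn reference", {
  set.seed(41)
  n <- 12; len <- 6
  X <- matrix(rnorm(n * len), n, len)
  X[7:12, ] <- X[7:12, ] + 3
  labels <- rep(1:2, each = 6)
  centers <- list(colMeans(X[1:6, ]), colMeans(X[7:12, ]))
  mine <- davies_bouldin(lapply(seq_len(n), function(i) X[i, ]),
                         labels, centers, metric = "euclidean")
  csv <- tempfile(fileext = ".csv")
  utils::write.table(cbind(labels, X), csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import numpy as np; from sklearn.metrics import davies_bouldin_score; ",
    "d = np.loadtxt('", csv, "', delimiter=','); ",
    "print(repr(davies_bouldin_score(d[:,1:], d[:,0])))"))),
    stdout = TRUE, stderr = TRUE))
  ref <- as.numeric(out[length(out)])
  expect_equal(mine, ref, tolerance = 1e-9)
})
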