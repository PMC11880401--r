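# Independent oracles used only by the tests.

# Brute-force DTW by full enumeration of all admissible warp paths
# (steps right/down/diagonal, endpoints pinned). Exponential; use only for
# tiny series.
dtw_enum_oracle <- function(x, y) {
  M <- length(x); N <- length(y)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + (x[i] - y[j])^2
    if (acc >= best) return(invisible(NULL))
    if (i == M && j == N) {
      best <<- acc
      return(invisible(NULL))
    }
    if (i < M && j < N) rec(i + 1, j + 1, acc)
    if (i < M) rec(i + 1, j, acc)
    if (j < N) rec(i, j + 1, acc)
    invisible(NULL)
  }
  rec(1, 1, 0)
  sqrt(best)
}

# Memoized top-down recursion on the minimal accumulated cost; independent
# of the package's iterative DP code path.
dtw_memo_oracle <- function(x, y) {
  M <- length(x); N <- length(y)
  memo <- matrix(NA_real_, M, N)
  cost <- function(i, j) {
    if (i < 1 || j < 1) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    prev <- if (i == 1 && j == 1) 0
            else min(cost(i - 1, j - 1), cost(i - 1, j), cost(i, j - 1))
    memo[i, j] <<- (x[i] - y[j])^2 + prev
    memo[i, j]
  }
  sqrt(cost(M, N))
}

# Exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments (untied data), mirroring the exact-distribution convention of
# the standard test.
mw_enum_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  u_all <- apply(combs, 2, function(id) sum(r[id]) - m * (m + 1) / 2)
  if (u_obs > m * n / 2) {
    p <- 2 * mean(u_all >= u_obs)
  } else {
    p <- 2 * mean(u_all <= u_obs)
  }
  min(p, 1)
}

# Valid warp path predicate.
is_valid_warp_path <- function(path, M, N) {
  if (!all(path[1, ] == c(1, 1))) return(FALSE)
  if (!all(path[nrow(path), ] == c(M, N))) return(FALSE)
  st <- diff(path)
  all(st[, 1] %in% 0:1) && all(st[, 2] %in% 0:1) &&
    all(rowSums(st) >= 1)
}
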