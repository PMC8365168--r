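# Independent oracles, written against the definitions rather than the
# package internals.

# Brute-force recursive DDTW: linear resample, Keogh-Pazzani derivative,
# then a memoised recursion over warping paths with squared local cost.
# Predecessor ties prefer diagonal, then vertical, then horizontal.
oracle_ddtw <- function(a, b, resample_len = 50) {
  rs <- function(x, L) {
    if (length(x) == L) return(as.numeric(x))
    stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = L))$y
  }
  der <- function(q) {
    n <- length(q)
    d <- vapply(2:(n - 1), function(i)
      ((q[i] - q[i - 1]) + (q[i + 1] - q[i - 1]) / 2) / 2, numeric(1))
    c(d[1], d, d[n - 2])
  }
  da <- der(rs(a, resample_len)); db <- der(rs(b, resample_len))
  n <- length(da); m <- length(db)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cost <- (da[i] - db[j])^2
    res <- if (i == 1 && j == 1) c(cost, 1)
    else if (i == 1) { p <- rec(1, j - 1); c(p[1] + cost, p[2] + 1) }
    else if (j == 1) { p <- rec(i - 1, 1); c(p[1] + cost, p[2] + 1) }
    else {
      best <- rec(i - 1, j - 1)
      up <- rec(i - 1, j); le <- rec(i, j - 1)
      if (up[1] < best[1]) best <- up
      if (le[1] < best[1]) best <- le
      c(best[1] + cost, best[2] + 1)
    }
    memo[[key]] <- res
    res
  }
  r <- rec(n, m)
  sqrt(r[1] / r[2])
}

# All permutations of seq_len(n), own recursion.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

# Exact permutation expectation of the interval compression ratio.
exact_compression_expectation <- function(onsets) {
  actual <- mean(abs(diff(onsets)))
  ms <- vapply(all_perms(length(onsets)),
               function(p) mean(abs(diff(onsets[p]))), numeric(1))
  mean(ms) / actual
}

# Closed-form OLS slope and its standard error.
ols_slope <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  s2 <- sum((y - a - b * x)^2) / (n - 2)
  c(slope = b, sem = sqrt(s2 / sum((x - mean(x))^2)))
}
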