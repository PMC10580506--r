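# shared fixtures and independent oracles, built in code at test time

grid15 <- seq(0, 300, by = 15)

ramp_trace <- function(from = 6, to = 10, times = grid15, ...) {
  glucose_trace(times, seq(from, to, length.out = length(times)), ...)
}

constant_trace <- function(value = 7, times = grid15, ...) {
  glucose_trace(times, rep(value, length(times)), ...)
}

random_trace <- function(times = grid15, lo = 3, hi = 13, ...) {
  glucose_trace(times, runif(length(times), lo, hi), ...)
}

# Riemann-sum AUC oracle on the piecewise-linear interpolant (fine grid)
riemann_auc <- function(trace, t_end, n = 20000L) {
  tt <- seq(0, t_end, length.out = n + 1L)
  vv <- approx(trace$times, trace$values, xout = tt)$y
  sum((vv[-1] + vv[-length(vv)]) / 2) * (t_end / n)
}

# brute-force count of below-threshold runs
brute_episode_count <- function(values, threshold = 3.9) {
  below <- values < threshold
  sum(diff(c(FALSE, below)) == 1)
}

# brute-force MAGE: scan extrema directly on the deduplicated series
brute_mage <- function(values) {
  s <- sd(values)
  u <- values[c(TRUE, diff(values) != 0)]
  if (length(u) < 2) return(0)
  ext <- u[1]
  for (i in 2:(length(u) - 1)) {
    if ((u[i] - u[i - 1]) * (u[i + 1] - u[i]) < 0) ext <- c(ext, u[i])
  }
  ext <- c(ext, u[length(u)])
  amp <- diff(ext)
  qual <- abs(amp) > s
  if (!any(qual)) return(0)
  dir <- sign(amp[which(qual)[1]])
  mean(abs(amp[qual & sign(amp) == dir]))
}

# brute-force exact two-sided signed-rank p over all 2^n sign assignments
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    pos <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    vs[mask + 1] <- sum(r[pos])
  }
  min(1, 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9)))
}
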