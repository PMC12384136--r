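# Independent brute-force oracles: everything here is computed term by term
# with explicit loops, never through the package's vectorized paths.

oracle_mean_squares <- function(m) {
  dimnames(m) <- NULL
  n <- nrow(m)
  k <- ncol(m)
  g <- mean(m)
  rowm <- numeric(n)
  for (i in seq_len(n)) rowm[i] <- mean(m[i, ])
  colm <- numeric(k)
  for (j in seq_len(k)) colm[j] <- mean(m[, j])
  ssb <- 0
  for (i in seq_len(n)) ssb <- ssb + k * (rowm[i] - g)^2
  ssr <- 0
  for (j in seq_len(k)) ssr <- ssr + n * (colm[j] - g)^2
  sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (m[i, j] - rowm[i] - colm[j] + g)^2
    }
  }
  list(msb = ssb / (n - 1), msr = ssr / (k - 1),
       msw = sse / ((n - 1) * (k - 1)),
       ssb = ssb, ssr = ssr, sse = sse)
}

oracle_icc <- function(m) {
  dimnames(m) <- NULL
  ms <- oracle_mean_squares(m)
  n <- nrow(m)
  k <- ncol(m)
  (ms$msb - ms$msw) /
    (ms$msb + (k - 1) * ms$msw + (k / n) * (ms$msr - ms$msw))
}

oracle_moment <- function(m, p, q) {
  dimnames(m) <- NULL
  n <- nrow(m)
  xb <- mean(m[, 1])
  yb <- mean(m[, 2])
  s <- 0
  for (i in seq_len(n)) s <- s + (m[i, 1] - xb)^p * (m[i, 2] - yb)^q
  s / n
}

oracle_tau <- function(m) {
  dimnames(m) <- NULL
  sqrt(oracle_moment(m, 2, 2) / (oracle_moment(m, 2, 0) * oracle_moment(m, 0, 2)))
}

# straight-loop permutation test: shuffle column 2, recompute the statistic
# from scratch each time; strict exceedance over B; same RNG stream contract
# as the package (set.seed(seed), then sample.int(n) B times in order)
oracle_perm_pvalue <- function(m, B, seed, studentized) {
  stat <- function(mm) {
    if (studentized) oracle_icc(mm) / oracle_tau(mm) else oracle_icc(mm)
  }
  obs <- stat(m)
  set.seed(seed)
  count <- 0
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(m))
    if (stat(cbind(m[, 1], m[idx, 2])) > obs) count <- count + 1
  }
  count / B
}

# bivariate normal with correlation rho, built independently of the package
oracle_bvn <- function(n, rho) {
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
}

# half-width of a 3-standard-error Monte Carlo band around a reference rate,
# combining the uncertainty of this run with that of a 10,000-replicate
# reference tabulation
mc_band <- function(rate_ref, n_reps, n_ref = 10000) {
  3 * sqrt(rate_ref * (1 - rate_ref) / n_reps +
           rate_ref * (1 - rate_ref) / n_ref)
}
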