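#' Two-way ANOVA mean squares for a two-rater ratings matrix
#'
#' Decomposes the total variation of an `n x 2` ratings matrix under the
#' two-way random-effects model
#' \deqn{x_{ij} = \mu + s_i + r_j + e_{ij},}
#' with subject effects \eqn{s_i \sim (0, \sigma_s^2)}, rater effects
#' \eqn{r_j \sim (0, \sigma_r^2)} and residuals
#' \eqn{e_{ij} \sim (0, \sigma_e^2)}, one observation per subject-rater cell.
#'
#' @param ratings A [ratings_matrix()] (or object coercible to one).
#'
#' @return A list of class `"icc_anova"` with components:
#' \describe{
#'   \item{msb}{mean square between subjects,
#'     \eqn{k \sum_i (\bar x_{i.} - \bar x_{..})^2 / (n-1)};
#'     \eqn{E(MSB) = \sigma_e^2 + k\sigma_s^2}.}
#'   \item{msr}{mean square for raters,
#'     \eqn{n \sum_j (\bar x_{.j} - \bar x_{..})^2 / (k-1)};
#'     \eqn{E(MSR) = \sigma_e^2 + n\sigma_r^2}.}
#'   \item{msw}{residual (subject-by-rater interaction) mean square,
#'     \eqn{SSE / ((n-1)(k-1))}; \eqn{E(MSW) = \sigma_e^2}.}
#'   \item{ssb, ssr, sse, sst}{the corresponding sums of squares
#'     (`ssb + ssr + sse == sst` up to rounding).}
#'   \item{n, k}{subject and rater counts (`k` is always 2).}
#' }
#'
#' @details `msw` here is the *two-way* residual mean square, not the pooled
#'   one-way within-subject mean square; the two differ by the rater sum of
#'   squares. The two-way form is the one consistent with a model that has a
#'   random rater term and with an ICC definition that uses `msr` separately.
#'   "MSW" is overloaded in the reliability literature, so this is worth
#'   stating: here \eqn{MSW = \sum_{ij} (x_{ij} - \bar x_{i.} - \bar x_{.j} +
#'   \bar x_{..})^2 / ((n-1)(k-1))}.
#'
#' @seealso [icc21()] for the agreement coefficient built from these.
#' @examples
#' ms <- mean_squares(ratings_matrix(c(1, 2, 3, 4, 5), c(2, 2, 4, 4, 6)))
#' ms$msb / ms$msw
#' @export
mean_squares <- function(ratings) {
  r <- as_ratings(ratings)
  n <- nrow(r)
  k <- 2L
  grand <- mean(r)
  rowm <- rowMeans(r)
  colm <- colMeans(r)
  ssb <- k * sum((rowm - grand)^2)
  ssr <- n * sum((colm - grand)^2)
  # residuals of the additive two-way fit; keeps SSE >= 0 exactly
  resid <- r - outer(rowm, c(1, 1)) - outer(rep(1, n), colm) + grand
  sse <- sum(resid^2)
  sst <- sum((r - grand)^2)
  structure(
    list(msb = ssb / (n - 1), msr = ssr / (k - 1),
         msw = sse / ((n - 1) * (k - 1)),
         ssb = ssb, ssr = ssr, sse = sse, sst = sst,
         n = n, k = k),
    class = "icc_anova")
}

#' @export
print.icc_anova <- function(x, ...) {
  cat("Two-way ANOVA mean squares (", x$n, " subjects, ", x$k, " raters)\n",
      sep = "")
  cat(sprintf("  MSB (subjects): %.6g\n  MSR (raters):   %.6g\n  MSW (residual): %.6g\n",
              x$msb, x$msr, x$msw))
  invisible(x)
}

#' Point estimate of ICC(2,1) with variance diagnostics
#'
#' Estimates the single-measure, absolute-agreement intraclass correlation
#' under the two-way random-effects model,
#' \deqn{\widehat{ICC}(2,1) = \frac{MSB - MSW}{MSB + (k-1) MSW +
#'   \frac{k}{n}(MSR - MSW)},}
#' together with two candidate variance quantities: the classical
#' large-sample variance of the estimate (unstable near \eqn{\rho = 0}, kept
#' as a diagnostic only) and the moment-based surrogate \eqn{\hat\tau_n^2}
#' used to studentize the permutation test statistic.
#'
#' @inheritParams mean_squares
#'
#' @return A list of class `"icc21"` with components:
#' \describe{
#'   \item{rho_hat}{the ICC(2,1) estimate. Negative values are returned
#'     as-is, never truncated at 0 (truncation would bias the permutation
#'     null distribution).}
#'   \item{u_hat}{\eqn{\hat u = k(MSR - MSW) / (n(MSB - MSW))}; `NA` when
#'     `MSB == MSW` (the ratio is undefined there).}
#'   \item{var_eq2}{classical large-sample variance
#'     \eqn{2\hat\rho^4 [(1/\hat\rho - 1)^2 + nk\hat u^2]}; `NA` when
#'     `u_hat` is undefined or \eqn{\hat\rho = 0}. Diagnostic only: it is
#'     not a usable studentizer near the null.}
#'   \item{tau_n2}{the moment surrogate
#'     \eqn{\hat\tau_n^2 = \hat\mu_{22} / (\hat\mu_{20}\hat\mu_{02})}
#'     (see [tau_n()]); `NA` if either column is constant.}
#'   \item{means}{the per-rater sample means \eqn{(\bar x_1, \bar x_2)}.}
#'   \item{ms}{the underlying [mean_squares()] object.}
#' }
#'
#' @details The estimate is exactly 1 when the two columns are identical and
#'   non-constant (then `MSW == MSR == 0`), and is invariant to adding a
#'   common constant to all entries, to multiplying all entries by a positive
#'   constant, and to swapping the two raters. A fully constant matrix makes
#'   the denominator zero and is rejected as degenerate.
#'
#' @examples
#' set.seed(1)
#' x <- rnorm(20); icc21(ratings_matrix(x, x + rnorm(20, sd = 0.3)))
#' @export
icc21 <- function(ratings) {
  r <- as_ratings(ratings)
  ms <- mean_squares(r)
  n <- ms$n
  k <- ms$k
  denom <- ms$msb + (k - 1) * ms$msw + (k / n) * (ms$msr - ms$msw)
  if (denom == 0) {
    stop("degenerate ratings: denominator of the ICC(2,1) formula is zero ",
         "(all entries equal)", call. = FALSE)
  }
  rho <- (ms$msb - ms$msw) / denom
  if (ms$msb != ms$msw) {
    u <- k * (ms$msr - ms$msw) / (n * (ms$msb - ms$msw))
    v <- if (rho != 0) 2 * rho^4 * ((1 / rho - 1)^2 + n * k * u^2) else NA_real_
  } else {
    u <- NA_real_
    v <- NA_real_
  }
  m20 <- central_moment(r, 2L, 0L)
  m02 <- central_moment(r, 0L, 2L)
  t2 <- if (m20 > 0 && m02 > 0) central_moment(r, 2L, 2L) / (m20 * m02) else NA_real_
  structure(
    list(rho_hat = rho, u_hat = u, var_eq2 = v, tau_n2 = t2,
         means = colMeans(r), ms = ms),
    class = "icc21")
}

#' @export
print.icc21 <- function(x, digits = 4, ...) {
  cat("ICC(2,1), absolute agreement, single measure\n")
  cat("  estimate:   ", format(x$rho_hat, digits = digits), "\n", sep = "")
  cat("  tau_n^2:    ", format(x$tau_n2, digits = digits),
      "  (moment studentizer)\n", sep = "")
  cat("  rater means:", paste(format(x$means, digits = digits), collapse = ", "),
      "\n")
  invisible(x)
}

#' Sample central cross-moment of the two rating columns
#'
#' \deqn{\hat\mu_{pq} = \frac{1}{n} \sum_{i=1}^n
#'   (x_{i1} - \bar x_1)^p (x_{i2} - \bar x_2)^q}
#' with divisor `n`, not `n - 1`.
#'
#' @inheritParams mean_squares
#' @param p,q Non-negative integer exponents for the first and second
#'   column, respectively.
#' @return The moment, a single number.
#' @export
central_moment <- function(ratings, p, q) {
  r <- as_ratings(ratings)
  if (length(p) != 1L || length(q) != 1L || p < 0 || q < 0 ||
      p != round(p) || q != round(q)) {
    stop("'p' and 'q' must be single non-negative integers", call. = FALSE)
  }
  a <- r[, 1L] - mean(r[, 1L])
  b <- r[, 2L] - mean(r[, 2L])
  mean(a^p * b^q)
}

#' Moment-based studentizer for the ICC permutation statistic
#'
#' Returns \eqn{\hat\tau_n = \sqrt{\hat\mu_{22} /
#' (\hat\mu_{20}\hat\mu_{02})}}, the large-sample standard deviation of the
#' sample correlation scaled by \eqn{\sqrt n}. It serves as a variance
#' surrogate for the ICC(2,1) estimate: when the rater effect is weak and
#' the two raters have similar spread, the between-subject and residual mean
#' squares align with the covariance and variances entering the correlation
#' coefficient. Dividing the ICC estimate by \eqn{\hat\tau_n} makes its
#' permutation distribution asymptotically pivotal, which is what restores
#' type-I-error control when the two columns are dependent but uncorrelated.
#'
#' @inheritParams mean_squares
#' @return The positive square root of \eqn{\hat\mu_{22} /
#'   (\hat\mu_{20}\hat\mu_{02})}. Under independent columns it converges
#'   to 1.
#' @export
tau_n <- function(ratings) {
  r <- as_ratings(ratings)
  m20 <- central_moment(r, 2L, 0L)
  m02 <- central_moment(r, 0L, 2L)
  if (m20 == 0 || m02 == 0) {
    stop("degenerate ratings: a constant rater column makes the ",
         "studentizer undefined", call. = FALSE)
  }
  sqrt(central_moment(r, 2L, 2L) / (m20 * m02))
}

# --- internal sums-based kernels shared with the permutation fast path ----
#
# For k = 2 everything reduces to column-centered sums. Writing a = x - xbar,
# b = y - ybar, Saa = sum(a^2), Sbb = sum(b^2), Sab = sum(a*b):
#   SSB = sum(a+b)^2/2, SSE = sum(a-b)^2/2, SSR = n (xbar-ybar)^2 / 2,
# so MSB - MSW = 2 Sab/(n-1) and MSB + MSW = (Saa+Sbb)/(n-1). Permuting the
# second column changes only Sab (and mu22), which is what makes the
# permutation loop a pair of matrix products.

icc_from_sums <- function(n, saa, sbb, sab, msr) {
  msb <- (saa + 2 * sab + sbb) / (2 * (n - 1))
  msw <- (saa - 2 * sab + sbb) / (2 * (n - 1))
  (msb - msw) / (msb + msw + (2 / n) * (msr - msw))
}
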