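#' @name agreement_tests
#' @title Tests of H0: ICC(2,1) = 0 against H1: ICC(2,1) > 0
#'
#' @description Four one-sided tests of zero intraclass correlation for two
#' raters: the classical ANOVA F test, Fisher's Z test, the naive
#' permutation test on the raw ICC estimate, and the studentized permutation
#' test (the headline method — it alone keeps its nominal level when the two
#' rating columns are dependent but uncorrelated, or have unequal marginals,
#' situations where permutation exchangeability fails).
#'
#' All four return an object of class `"icc_test"`: a list with `method`
#' (one of `"f_test"`, `"fisher_z"`, `"permute"`, `"stu_permute"`),
#' `statistic`, `p_value`, `n_permutations` (0 for the non-permutation
#' tests), `seed` (NA for deterministic tests), `alpha` and `reject`
#' (`p_value <= alpha`, the non-strict convention).
NULL

new_icc_test <- function(method, statistic, p_value, B = 0L, seed = NA_integer_,
                         alpha = 0.05, rho_hat = NA_real_) {
  structure(
    list(method = method, statistic = statistic, p_value = p_value,
         n_permutations = as.integer(B), seed = seed, alpha = alpha,
         reject = p_value <= alpha, rho_hat = rho_hat),
    class = "icc_test")
}

#' @export
print.icc_test <- function(x, digits = 4, ...) {
  lab <- c(f_test = "ANOVA F test", fisher_z = "Fisher's Z test",
           permute = "permutation test (naive)",
           stu_permute = "studentized permutation test")[x$method]
  cat(lab, "of H0: ICC(2,1) = 0 vs H1: ICC(2,1) > 0\n")
  cat("  statistic = ", format(x$statistic, digits = digits),
      ", p-value = ", format(x$p_value, digits = digits), "\n", sep = "")
  if (x$n_permutations > 0) {
    cat("  B = ", x$n_permutations, " permutations, seed = ", x$seed, "\n",
        sep = "")
  }
  cat("  ", if (x$reject) "reject" else "do not reject",
      " H0 at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' ANOVA F test for zero ICC(2,1)
#'
#' The classical reliability F test in its one-way form: the between-subject
#' mean square over the pooled within-subject mean square,
#' `F = MSB / ((SSR + SSE) / (n(k-1)))`, referred to an F distribution with
#' `n - 1` and `n(k - 1)` degrees of freedom, upper tail. Under the zero
#' null the subject effect vanishes, so pooling the rater and residual sums
#' of squares in the denominator is exact under normality. Its level is only
#' guaranteed under bivariate normality; under heavy tails or dependence
#' without correlation its rejection rate can converge to an arbitrary value
#' on either side of the nominal level.
#'
#' @inheritParams mean_squares
#' @param alpha Nominal level used for the reject flag.
#' @return An `"icc_test"` object, method `"f_test"`.
#' @export
icc_f_test <- function(ratings, alpha = 0.05) {
  r <- as_ratings(ratings)
  ms <- mean_squares(r)
  msw1 <- (ms$ssr + ms$sse) / (ms$n * (ms$k - 1))
  if (msw1 == 0) {
    stop("degenerate ratings: within-subject mean square is zero (perfect ",
         "agreement), F test undefined", call. = FALSE)
  }
  f <- ms$msb / msw1
  df1 <- ms$n - 1
  df2 <- ms$n * (ms$k - 1)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  new_icc_test("f_test", f, p, alpha = alpha, rho_hat = icc21(r)$rho_hat)
}

#' Fisher's Z test for zero ICC(2,1)
#'
#' Fisher's variance-stabilizing transformation applied to the ICC
#' estimate with the correlation-coefficient standard error:
#' `z = atanh(rho_hat) * sqrt(n - 3)`, referred to the standard normal
#' upper tail. Like the F test it leans on bivariate normality; under
#' non-normal data its standard error is mis-calibrated and the test is
#' typically strongly conservative, markedly so at small n.
#'
#' @inheritParams icc_f_test
#' @return An `"icc_test"` object, method `"fisher_z"`.
#' @export
icc_fisher_z_test <- function(ratings, alpha = 0.05) {
  r <- as_ratings(ratings)
  rho <- icc21(r)$rho_hat
  if (abs(rho) >= 1) {
    stop("degenerate ratings: |ICC estimate| = 1, Fisher transform ",
         "undefined", call. = FALSE)
  }
  z <- atanh(rho) * sqrt(nrow(r) - 3)
  p <- stats::pnorm(z, lower.tail = FALSE)
  new_icc_test("fisher_z", z, p, alpha = alpha, rho_hat = rho)
}

# Vectorized permutation kernel. Shuffles only the second rater's column; B
# permutations are drawn as sample.int(n) B times in order from the current
# RNG state (this exact stream is the reproducibility contract with callers
# and with the straight-loop reference used in the tests). The observed
# statistic is computed through the same matrix path as the permuted ones
# (column 1 of the index matrix is the identity) so that a permutation that
# happens to reproduce the observed pairing yields an exact float tie and is
# never counted as exceeding.
perm_kernel <- function(x, y, B) {
  n <- length(x)
  a <- x - mean(x)
  b <- y - mean(y)
  saa <- sum(a^2)
  sbb <- sum(b^2)
  msr <- n * (mean(x) - mean(y))^2 / 2  # invariant under shuffles of y
  idx <- matrix(0L, n, B + 1L)
  idx[, 1L] <- seq_len(n)
  for (k in seq_len(B)) idx[, k + 1L] <- sample.int(n)
  bp <- matrix(b[idx], n, B + 1L)
  sab <- as.vector(crossprod(a, bp))
  mu22 <- as.vector(crossprod(a^2, bp^2)) / n
  rho <- icc_from_sums(n, saa, sbb, sab, msr)
  tau2 <- mu22 / ((saa / n) * (sbb / n))
  list(rho_obs = rho[1L], rho_perm = rho[-1L],
       tau2_obs = tau2[1L], tau2_perm = tau2[-1L])
}

# p-value from permuted vs observed statistics: strict exceedance over B,
# no add-one smoothing. Undefined permuted statistics count as non-exceeding.
perm_pvalue <- function(stat_obs, stat_perm) {
  und <- !is.finite(stat_perm)
  if (any(und)) {
    warning("permuted studentizer undefined in ", sum(und),
            " replicate(s); counted as non-exceeding", call. = FALSE)
    stat_perm <- stat_perm[!und]
  }
  sum(stat_perm > stat_obs) / (length(stat_perm) + sum(und))
}

#' Permutation tests for zero ICC(2,1)
#'
#' One-sided permutation test of `H0: ICC(2,1) = 0`. The second rater's
#' column is randomly shuffled `B` times (the first column's order is
#' fixed); the test statistic is recomputed on each permuted pairing,
#' including the rater mean square, and the p-value is the strict
#' exceedance fraction
#' \deqn{p = \frac{1}{B} \sum_{k=1}^{B} I(R_k > R),}
#' so `p * B` is an integer and `p = 0` is attainable. `H0` is rejected
#' when `p <= alpha` (non-strict).
#'
#' With `studentized = TRUE` (the recommended default) the statistic is
#' \eqn{R = \hat\rho / \hat\tau_n} with the moment studentizer of
#' [tau_n()]; this version is asymptotically exact even when permutation
#' exchangeability fails. With `studentized = FALSE` the raw estimate
#' \eqn{\hat\rho} is used (the naive test, kept as a benchmark — it
#' over-rejects under dependence without correlation).
#'
#' @inheritParams icc_f_test
#' @param B Number of random permutations (at least 1).
#' @param seed Integer seed for the permutation stream; if `NULL`, one is
#'   drawn and recorded in the result. The same `(data, B, seed)` always
#'   reproduces the same p-value.
#' @param studentized Use the studentized statistic (default `TRUE`)?
#' @return An `"icc_test"` object, method `"stu_permute"` or `"permute"`.
#' @examples
#' set.seed(7)
#' r <- generate_scenario("mvn", n = 25, seed = 7)
#' icc_permutation_test(r, B = 500, seed = 1)
#' @export
icc_permutation_test <- function(ratings, B = 1000L, seed = NULL,
                                 studentized = TRUE, alpha = 0.05) {
  r <- as_ratings(ratings)
  if (length(B) != 1L || B < 1 || B != round(B)) {
    stop("'B' must be a single positive integer", call. = FALSE)
  }
  if (studentized &&
      (stats::var(r[, 1L]) == 0 || stats::var(r[, 2L]) == 0)) {
    stop("degenerate ratings: a constant rater column makes the ",
         "studentizer undefined", call. = FALSE)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  kern <- perm_kernel(r[, 1L], r[, 2L], as.integer(B))
  if (studentized) {
    if (kern$tau2_obs == 0) {
      stop("degenerate ratings: observed studentizer is zero", call. = FALSE)
    }
    stat_obs <- kern$rho_obs / sqrt(kern$tau2_obs)
    stat_perm <- kern$rho_perm / sqrt(kern$tau2_perm)
    method <- "stu_permute"
  } else {
    stat_obs <- kern$rho_obs
    stat_perm <- kern$rho_perm
    method <- "permute"
  }
  p <- perm_pvalue(stat_obs, stat_perm)
  new_icc_test(method, stat_obs, p, B = B, seed = as.integer(seed),
               alpha = alpha, rho_hat = kern$rho_obs)
}

#' Run all four agreement tests on one ratings matrix
#'
#' Applies the F test, Fisher's Z test, and the naive and studentized
#' permutation tests to the same data. The two permutation tests share the
#' same `B` shuffles (one seed stream), so their contrast is not confounded
#' by permutation noise.
#'
#' @inheritParams icc_permutation_test
#' @return A named list of class `"icc_test_list"` with one `"icc_test"`
#'   per method. A method whose preconditions fail (e.g. the F test on a
#'   perfect-agreement matrix) is replaced by a record with the error
#'   message under `$error`.
#' @examples
#' set.seed(2)
#' icc_test_all(generate_power(0.6, n = 30, seed = 2), B = 500, seed = 9)
#' @export
icc_test_all <- function(ratings, B = 1000L, seed = NULL, alpha = 0.05) {
  r <- as_ratings(ratings)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  out <- list()
  for (m in c("f_test", "fisher_z")) {
    fn <- if (m == "f_test") icc_f_test else icc_fisher_z_test
    out[[m]] <- tryCatch(fn(r, alpha = alpha), error = function(e) {
      structure(list(method = m, error = conditionMessage(e)),
                class = "icc_test_error")
    })
  }
  perm <- tryCatch({
    set.seed(seed)
    kern <- perm_kernel(r[, 1L], r[, 2L], as.integer(B))
    naive <- new_icc_test("permute", kern$rho_obs,
                          perm_pvalue(kern$rho_obs, kern$rho_perm),
                          B = B, seed = as.integer(seed), alpha = alpha,
                          rho_hat = kern$rho_obs)
    stu <- if (kern$tau2_obs > 0) {
      new_icc_test("stu_permute", kern$rho_obs / sqrt(kern$tau2_obs),
                   perm_pvalue(kern$rho_obs / sqrt(kern$tau2_obs),
                               kern$rho_perm / sqrt(kern$tau2_perm)),
                   B = B, seed = as.integer(seed), alpha = alpha,
                   rho_hat = kern$rho_obs)
    } else {
      structure(list(method = "stu_permute",
                     error = "observed studentizer is zero"),
                class = "icc_test_error")
    }
    list(permute = naive, stu_permute = stu)
  }, error = function(e) {
    msg <- conditionMessage(e)
    list(permute = structure(list(method = "permute", error = msg),
                             class = "icc_test_error"),
         stu_permute = structure(list(method = "stu_permute", error = msg),
                                 class = "icc_test_error"))
  })
  out <- c(out, perm)
  structure(out, class = "icc_test_list")
}

#' @export
print.icc_test_list <- function(x, ...) {
  for (t in x) {
    if (inherits(t, "icc_test_error")) {
      cat(t$method, ": error - ", t$error, "\n", sep = "")
    } else {
      print(t, ...)
    }
  }
  invisible(x)
}
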