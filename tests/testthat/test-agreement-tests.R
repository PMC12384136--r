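test_that("F statistic transcribes the oracle ANOVA and is location invariant", {
  set.seed(3)
  m <- ratings_matrix(rnorm(12), rnorm(12))
  ft <- icc_f_test(m)
  o <- oracle_mean_squares(unclass(m))
  f_o <- o$msb / ((o$ssr + o$sse) / 12)
  expect_equal(ft$statistic, f_o, tolerance = 1e-12)
  expect_equal(ft$p_value, pf(f_o, 11, 12, lower.tail = FALSE),
               tolerance = 1e-12)
  shifted <- icc_f_test(ratings_matrix(unclass(m) + 7.3))
  expect_equal(shifted$statistic, ft$statistic, tolerance = 1e-10)

  expect_error(icc_f_test(ratings_matrix(1:4, 1:4)), "degenerate")
})

test_that("Fisher Z statistic is atanh(rho_hat) * sqrt(n - 3/2)", {
  set.seed(4)
  m <- ratings_matrix(rnorm(15), rnorm(15))
  zt <- icc_fisher_z_test(m)
  expect_equal(zt$statistic, atanh(oracle_icc(unclass(m))) * sqrt(15 - 3),
               tolerance = 1e-12)
  expect_equal(zt$p_value, pnorm(zt$statistic, lower.tail = FALSE),
               tolerance = 1e-12)

  # rho_hat exactly zero (orthogonal centered columns): z = 0, p = 1/2
  m0 <- ratings_matrix(c(1, 2, 3), c(1, 0, 1))
  z0 <- icc_fisher_z_test(m0)
  expect_equal(z0$statistic, 0, tolerance = 1e-12)
  expect_equal(z0$p_value, 0.5, tolerance = 1e-12)

  expect_error(icc_fisher_z_test(ratings_matrix(1:4, 1:4)), "degenerate")
})

test_that("permutation p-values are strict-exceedance multiples of 1/B and reproducible", {
  set.seed(8)
  m <- ratings_matrix(rnorm(20), rnorm(20))
  t1 <- icc_permutation_test(m, B = 200, seed = 13)
  t2 <- icc_permutation_test(m, B = 200, seed = 13)
  expect_identical(t1$p_value, t2$p_value)
  expect_identical(t1$statistic, t2$statistic)
  expect_equal(t1$p_value * 200, round(t1$p_value * 200), tolerance = 1e-9)
  expect_gte(t1$p_value, 0)
  expect_lte(t1$p_value, 1)

  # a single permutation that reproduces the identity ordering is an exact
  # tie, and strict inequality forces p = 0
  id_seed <- NULL
  for (s in 1:5000) {
    set.seed(s)
    if (all(sample.int(5) == 1:5)) { id_seed <- s; break }
  }
  expect_false(is.null(id_seed))
  m5 <- ratings_matrix(c(0.3, 1.2, -0.5, 2.0, 0.7),
                       c(1.1, -0.4, 0.9, 0.2, 1.6))
  expect_identical(icc_permutation_test(m5, B = 1, seed = id_seed)$p_value, 0)
  expect_identical(
    icc_permutation_test(m5, B = 1, seed = id_seed, studentized = FALSE)$p_value,
    0)
})

test_that("p is monotone non-increasing in the observed statistic for fixed shuffles", {
  set.seed(21)
  m <- ratings_matrix(rnorm(15), rnorm(15))
  set.seed(99)
  kern <- iccperm:::perm_kernel(m[, 1], m[, 2], 100)
  stats_perm <- kern$rho_perm / sqrt(kern$tau2_perm)
  obs_grid <- sort(c(stats_perm, -2, 0, 2))
  p_grid <- vapply(obs_grid, function(o) iccperm:::perm_pvalue(o, stats_perm),
                   numeric(1))
  expect_true(all(diff(p_grid) <= 0))
})

test_that("fast-path permutation p-values equal a straight-loop oracle exactly", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(8:12, 1)
    B <- sample(30:100, 1)
    seed <- sample.int(10000, 1)
    studentized <- i %% 2 == 0
    m <- ratings_matrix(rnorm(n), 0.3 * rnorm(n) + rt(n, df = 3))
    fast <- icc_permutation_test(m, B = B, seed = seed,
                                 studentized = studentized)
    expect_identical(fast$p_value,
                     oracle_perm_pvalue(unclass(m), B, seed, studentized))
  }
})

test_that("constant-column inputs are rejected for the studentized test", {
  m <- ratings_matrix(rep(1, 5), rnorm(5))
  expect_error(icc_permutation_test(m, B = 10, seed = 1), "degenerate")
  # the naive statistic does not need the studentizer
  expect_s3_class(icc_permutation_test(m, B = 10, seed = 1,
                                       studentized = FALSE), "icc_test")
})

test_that("icc_test_all returns four entries, shares shuffles, and is deterministic", {
  set.seed(6)
  m <- ratings_matrix(rnorm(18), rnorm(18))
  all1 <- icc_test_all(m, B = 150, seed = 5)
  all2 <- icc_test_all(m, B = 150, seed = 5)
  expect_named(all1, c("f_test", "fisher_z", "permute", "stu_permute"))
  expect_identical(all1, all2)

  # the two permutation entries reproduce the standalone tests at that seed
  expect_identical(all1$permute$p_value,
                   icc_permutation_test(m, B = 150, seed = 5,
                                        studentized = FALSE)$p_value)
  expect_identical(all1$stu_permute$p_value,
                   icc_permutation_test(m, B = 150, seed = 5)$p_value)

  # degenerate data: per-method errors are recorded, not thrown
  ident <- ratings_matrix(1:5, 1:5)
  res <- icc_test_all(ident, B = 50, seed = 2)
  expect_length(res, 4)
  expect_s3_class(res$f_test, "icc_test_error")
  expect_s3_class(res$fisher_z, "icc_test_error")
})

test_that("all four tests detect strong agreement", {
  m <- ratings_matrix(oracle_bvn(50, 0.9))
  set.seed(17)
  res <- icc_test_all(ratings_matrix(m), B = 500, seed = 17)
  for (t in res) expect_lt(t$p_value, 0.05)
  # cross-checked against the straight-loop oracle
  expect_identical(res$stu_permute$p_value,
                   oracle_perm_pvalue(unclass(m), 500, 17, TRUE))
})

test_that("studentized permutation p-values are approximately uniform under an exchangeable null", {
  set.seed(71)
  n_reps <- 5000
  B <- 500
  pvals <- replicate(n_reps, {
    m <- cbind(rnorm(15), rnorm(15))
    kern <- iccperm:::perm_kernel(m[, 1], m[, 2], B)
    iccperm:::perm_pvalue(kern$rho_obs / sqrt(kern$tau2_obs),
                          kern$rho_perm / sqrt(kern$tau2_perm))
  })
  for (alpha in c(0.01, 0.05, 0.1)) {
    # strict-exceedance p-values are discrete: with B permutations the exact
    # rejection probability of an exchangeable statistic is
    # (floor(alpha * B) + 1) / (B + 1)
    expected <- (floor(alpha * B) + 1) / (B + 1)
    se <- sqrt(expected * (1 - expected) / n_reps)
    expect_lt(abs(mean(pvals <= alpha) - expected), 3 * se)
  }
})
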