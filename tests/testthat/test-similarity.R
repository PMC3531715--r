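test_that("pearson_r behaves at its edge cases", {
  set.seed(1)
  a <- rnorm(50)
  expect_equal(pearson_r(a, a), 1)
  expect_equal(pearson_r(a, -a), -1)
  t <- seq(0, 1 - 1 / 200, by = 1 / 200)
  expect_equal(pearson_r(sin(2 * pi * t), cos(2 * pi * t)), 0,
               tolerance = 1e-10)
  expect_warning(r <- pearson_r(rep(1, 10), rnorm(10)), "zero-variance")
  expect_true(is.na(r))
})

test_that("circular cross-correlation recovers known rotations", {
  set.seed(2)
  a <- abs(rnorm(200)) + 0.1
  b <- emgsynergy:::circshift(a, 10)  # b delayed by 10 samples = 5% of cycle
  sim <- circular_xcorr(a, b)
  expect_equal(sim$r_max, 1, tolerance = 1e-12)
  expect_equal(sim$lag_abs_pct, 5)
  self <- circular_xcorr(a, a)
  expect_equal(self$r, 1)
  expect_equal(self$r_max, 1)
  expect_equal(self$lag_pct, 0)
  t <- seq(0, 1 - 1 / 200, by = 1 / 200)
  quad <- circular_xcorr(sin(2 * pi * t), cos(2 * pi * t))
  expect_equal(quad$r_max, 1, tolerance = 1e-12)
  expect_equal(quad$lag_abs_pct, 25)
})

test_that("r_max dominates r and is invariant to rotations of either input", {
  set.seed(3)
  for (rep in 1:5) {
    a <- abs(rnorm(60))
    b <- abs(rnorm(60))
    s1 <- circular_xcorr(a, b)
    expect_gte(s1$r_max, s1$r)
    s2 <- circular_xcorr(a, emgsynergy:::circshift(b, sample(60, 1)))
    s3 <- circular_xcorr(emgsynergy:::circshift(a, sample(60, 1)), b)
    expect_equal(s2$r_max, s1$r_max, tolerance = 1e-12)
    expect_equal(s3$r_max, s1$r_max, tolerance = 1e-12)
  }
})

test_that("synergy matching recovers permutations and is optimal for s = 3", {
  W <- make_synergy_basis(10, 3, seed = 4)
  perm <- c(3, 1, 2)
  m <- match_synergies(W, W[, perm])
  expect_equal(m$permutation[perm], 1:3)  # inverse permutation recovered
  expect_equal(unname(m$r), rep(1, 3), tolerance = 1e-12)
  m_id <- match_synergies(W, W)
  expect_equal(m_id$permutation, 1:3)

  set.seed(5)
  Wa <- matrix(abs(rnorm(30)), 10)
  Wb <- matrix(abs(rnorm(30)), 10)
  m2 <- match_synergies(Wa, Wb)
  R <- cor(Wa, Wb)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  totals <- sapply(perms, function(p) sum(R[cbind(1:3, p)]))
  expect_equal(m2$total, max(totals), tolerance = 1e-12)
})

test_that("the analytic critical r matches the published cut-off and an F-quantile oracle", {
  expect_equal(round(critical_r(12, 0.01), 2), 0.71)
  # independent route via the F distribution: t^2 ~ F(1, df)
  crit_f <- function(p, alpha) {
    f <- qf(1 - alpha, 1, p - 2)
    sqrt(f / (f + p - 2))
  }
  expect_equal(critical_r(4, 0.05), crit_f(4, 0.05), tolerance = 1e-12)
  expect_equal(critical_r(30, 0.01), crit_f(30, 0.01), tolerance = 1e-12)
  # monotone decreasing in the number of muscles
  vals <- sapply(c(5, 8, 12, 20, 50), critical_r)
  expect_true(all(diff(vals) < 0))
  expect_error(critical_r(2), "at least 3")
  expect_error(critical_r(12, 1.5), "alpha")
})

test_that("permutation null bookkeeping and determinism", {
  W <- make_synergy_basis(12, 2, seed = 6)
  null1 <- permutation_null(list(W[, 1], W[, 2]), n_perm = 1, seed = 7)
  expect_length(null1$r_values, 1L)
  n2 <- permutation_null(cbind(W[, 1], W[, 2], W[, 1]), n_perm = 50, seed = 8)
  expect_length(n2$r_values, 3L * 50L)
  n2b <- permutation_null(cbind(W[, 1], W[, 2], W[, 1]), n_perm = 50, seed = 8)
  expect_identical(n2$r_values, n2b$r_values)
})

test_that("permutation null of generic weight profiles centres near zero with the expected tail", {
  # nine subjects sharing similar 12-muscle weight profiles
  W_list <- lapply(1:9, function(i) make_synergy_basis(12, 3, seed = i)[, 1])
  null <- permutation_null(W_list, n_perm = 300, seed = 9)
  expect_lt(abs(mean(null$r_values)), 0.1)
  expect_lt(null$percentile_99, 1)
  # chance-similarity threshold lands in the neighbourhood of the analytic r
  expect_gt(null$percentile_99, 0.60)
  expect_lt(null$percentile_99, 0.80)
})

test_that("pairwise similarity enumerates all unordered pairs and recovers known shifts", {
  set.seed(10)
  base <- abs(rnorm(200)) + 0.1
  nine <- lapply(1:9, function(i) base)
  ps <- pairwise_similarity(nine)
  expect_equal(nrow(ps$pairs), 36L)
  expect_equal(ps$summary$mean[ps$summary$index == "r"], 1)
  expect_equal(ps$summary$mean[ps$summary$index == "r_max"], 1)
  expect_equal(ps$summary$mean[ps$summary$index == "lag_abs_pct"], 0)

  shifted <- list(base, emgsynergy:::circshift(base, 10))
  ps2 <- pairwise_similarity(shifted)
  expect_equal(ps2$summary$mean[ps2$summary$index == "lag_abs_pct"], 5)
})
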