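test_that("Welch's t matches closed-form values", {
  wt <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(wt$t, -1.224745, tolerance = 1e-6)
  expect_equal(wt$df, 4, tolerance = 1e-9)
  expect_equal(wt$p, 0.2878641, tolerance = 1e-6)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # p decreases monotonically as the shift grows
  set.seed(5)
  a <- rnorm(50)
  ps <- vapply(c(0.5, 1, 2), function(c0) welch_t(a, a + c0)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("mean PSD averages pointwise and validates grids", {
  f <- seq(0.2, 100, by = 0.2)
  make <- function(p) structure(list(freq_hz = f, power = p),
                                class = "psd_estimate")
  p1 <- make(f^-2)
  expect_equal(mean_psd(list(p1))$power, p1$power)
  expect_equal(mean_psd(list(p1, p1))$power, p1$power)
  expect_equal(mean_psd(list(make(0.4 * f^-2), make(1.6 * f^-2)))$power,
               p1$power, tolerance = 1e-12)
  bad <- structure(list(freq_hz = f + 1, power = f^-2),
                   class = "psd_estimate")
  expect_error(mean_psd(list(p1, bad)), "grids differ")
})

test_that("mean-PSD slope comparison recovers known group differences", {
  f <- seq(0.2, 100, by = 0.2)
  make <- function(p) structure(list(freq_hz = f, power = p),
                                class = "psd_estimate")
  noisy <- function(b) make(f^b * exp(rnorm(length(f), sd = 0.02)))
  set.seed(9)
  ga <- list(noisy(-2.9), noisy(-2.9), noisy(-2.9))
  gb <- list(noisy(-2.5), noisy(-2.5), noisy(-2.5))
  cmp <- compare_mean_psd_slopes(ga, gb)
  expect_equal(cmp$slope_a - cmp$slope_b, -0.4, tolerance = 0.08)
  expect_lt(cmp$p_value, 0.001)
  # identical groups: no difference
  cmp0 <- compare_mean_psd_slopes(ga, ga)
  expect_equal(cmp0$slope_a, cmp0$slope_b)
  expect_equal(abs(cmp0$t_stat), 0, tolerance = 1e-8)
  # swapping labels flips the sign only
  rev <- compare_mean_psd_slopes(gb, ga)
  expect_equal(rev$t_stat, -cmp$t_stat, tolerance = 1e-8)
})

test_that("Shapiro-Wilk gate behaves as a normality test should", {
  set.seed(2)
  x <- rnorm(100)
  sw <- shapiro_wilk(x)
  expect_gt(sw$W, 0.97)
  # power against exponential samples
  rej <- mean(vapply(1:300, function(i) {
    set.seed(i)
    shapiro_wilk(rexp(100))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.8)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "n must be")
})

test_that("Grubbs' test flags a single gross outlier", {
  g <- grubbs_test(c(1, 2, 3, 100))
  expect_identical(g$outlier_idx, 4L)
  expect_equal(g$G, 1.499792, tolerance = 1e-5)
  expect_equal(g$G_crit, 1.48125, tolerance = 1e-4)
  expect_true(is.na(grubbs_test(c(1, 2, 3, 4))$outlier_idx))
  expect_true(is.na(grubbs_test(c(-1, 0, 1))$outlier_idx))
  expect_error(grubbs_test(c(1, 2)), "n >= 3")
})

test_that("Mann-Whitney U uses exact enumeration for small samples", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(mw$U), 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-9)
  expect_identical(mw$method, "exact")
  # identical samples: U = nA*nB/2 (ties force the normal approximation)
  mw2 <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unname(mw2$U), 8)
  expect_identical(mw2$method, "normal approximation")
  # extreme separation
  expect_equal(unname(mann_whitney_u(1:5, 101:105)$U), 0)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("summaries report mean and SEM", {
  s <- summarize_mean_sem(c(2, 4, 6))
  expect_equal(s$mean, 4)
  expect_equal(s$sem, 1.154701, tolerance = 1e-6)
  expect_warning(s1 <- summarize_mean_sem(5), "single observation")
  expect_equal(s1$sem, 0)
  s2 <- summarize_mean_sem(3 * c(2, 4, 6))
  expect_equal(s2$mean, 3 * s$mean)
  expect_equal(s2$sem, 3 * s$sem, tolerance = 1e-9)
})

test_that("tests are invariant to sample ordering", {
  set.seed(4)
  a <- rnorm(20)
  b <- rnorm(20, 0.5)
  for (f in list(welch_t, mann_whitney_u)) {
    r1 <- f(a, b)
    r2 <- f(sample(a), sample(b))
    expect_equal(r1[[1]], r2[[1]], tolerance = 1e-12)
    expect_equal(r1$p, r2$p, tolerance = 1e-12)
  }
})
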