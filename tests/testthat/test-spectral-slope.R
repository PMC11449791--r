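test_that("Welch PSD locates spectral peaks on an exact 0.2 Hz grid", {
  fs <- 1000
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  psd <- welch_psd(sin(2 * pi * 40 * tt), fs)
  expect_equal(diff(psd$freq_hz)[1], 0.2, tolerance = 1e-12)
  expect_equal(psd$freq_hz[which.max(psd$power)], 40)
})

test_that("Welch PSD satisfies Parseval and is flat for white noise", {
  set.seed(31)
  x <- rnorm(60000)
  psd <- welch_psd(x, 1000)
  total <- sum(psd$power) * psd$resolution_hz
  expect_lt(abs(total - var(x)) / var(x), 0.05)
  # flatness on synthesized white noise (deterministic spectral
  # amplitudes, so single-realization slope noise is small)
  sl <- vapply(1:3, function(s) {
    fit_slope(welch_psd(generate_colored_noise(0, 60000, 1000, seed = s),
                        1000))$b
  }, numeric(1))
  expect_lt(abs(mean(sl)), 0.1)
  expect_error(welch_psd(numeric(0), 1000), "empty")
})

test_that("fit_slope recovers exact power laws to machine precision", {
  f <- seq(0.2, 100, by = 0.2)
  make <- function(p) structure(list(freq_hz = f, power = p),
                                class = "psd_estimate")
  expect_equal(fit_slope(make(f^-3))$b, -3, tolerance = 1e-10)
  expect_equal(fit_slope(make(rep(2, length(f))))$b, 0, tolerance = 1e-10)
  fit <- fit_slope(make(10 * f^-2))
  expect_equal(fit$b, -2, tolerance = 1e-10)
  expect_equal(fit$a, 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-8)
})

test_that("fit_slope is scale-equivariant and handles bad points", {
  f <- seq(0.2, 100, by = 0.2)
  p <- f^-2.5 * exp(rnorm(length(f), sd = 0.1))
  make <- function(p) structure(list(freq_hz = f, power = p),
                                class = "psd_estimate")
  f1 <- fit_slope(make(p))
  f2 <- fit_slope(make(100 * p))
  expect_equal(f2$b, f1$b, tolerance = 1e-10)
  expect_equal(f2$a, f1$a + 2, tolerance = 1e-10)
  # non-positive powers are dropped with a message
  p2 <- p
  p2[c(160, 170)] <- 0     # inside the 30-50 band
  expect_message(f3 <- fit_slope(make(p2)), "non-positive")
  expect_equal(f3$n_points, f1$n_points - 2L)
  # too few usable points
  expect_error(fit_slope(make(p), band = c(30, 30.2)), "fewer than 3")
})

test_that("single-cycle periodograms concentrate energy where it belongs", {
  fs <- 1000
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- recording(sin(2 * pi * 40 * tt), fs)
  cyc <- data.frame(valley_left_idx = 1001L, valley_right_idx = 1125L)
  psd <- cycle_psd(rec, cyc)
  inband <- function(lo, hi) {
    sum(psd$power[psd$freq_hz >= lo & psd$freq_hz <= hi])
  }
  expect_gt(inband(30, 50), inband(50, 70))
  expect_equal(diff(psd$freq_hz)[1], 0.2, tolerance = 1e-12)
  # deterministic
  expect_identical(psd$power, cycle_psd(rec, cyc)$power)
  short <- data.frame(valley_left_idx = 1L, valley_right_idx = 50L)
  expect_error(cycle_psd(rec, short), "71 ms")
})

test_that("pooled PSD of cycles tiling a record matches the record PSD", {
  x <- generate_colored_noise(2, 30000, 1000, seed = 14)
  rec <- recording(x, 1000)
  starts <- seq(1, 29876, by = 125)
  cyc <- data.frame(valley_left_idx = starts,
                    valley_right_idx = starts + 124L)
  pooled <- pooled_theta_psd(rec, cyc, taper_ms = 0, hp_hz = 0)
  direct <- welch_psd(x, 1000)
  sel <- pooled$freq_hz >= 30 & pooled$freq_hz <= 50
  ratio <- pooled$power[sel] / direct$power[sel]
  expect_lt(max(abs(log10(ratio))), log10(1.1))
  expect_error(pooled_theta_psd(rec, cyc[0, ]), "no theta cycles")
})

test_that("the pipeline recovers a known exponent end to end", {
  sim <- generate_lfp(lfp_sim_params(duration_s = 60, beta = 2.5, seed = 17))
  res <- suppressMessages(theta_slope_pipeline(sim$rec))
  # single 60 s realization: sampling SD of the fit is ~0.15, so this is
  # a smoke test; the multi-seed recovery check lives in the acceptance
  # suite
  expect_lt(abs(res$pooled_fit$b + 2.5), 0.5)
  expect_equal(res$slopes, res$cycles$slope_30_50)
  expect_true(all(is.finite(res$slopes)))
})
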