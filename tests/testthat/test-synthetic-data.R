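test_that("colored noise recovers its spectral exponent", {
  # white noise: flat 30-50 Hz slope
  x <- generate_colored_noise(0, 2^16, fs = 1000, seed = 3)
  expect_lt(abs(fit_slope(welch_psd(x, 1000))$b), 0.1)
  # exponent sweep, mean over realizations
  for (beta in c(1, 2.5)) {
    sl <- vapply(1:20, function(s) {
      fit_slope(welch_psd(generate_colored_noise(beta, 60000, 1000,
                                                 seed = s), 1000))$b
    }, numeric(1))
    expect_lt(abs(mean(sl) + beta), 0.15)
  }
})

test_that("colored noise is deterministic, normalized and validated", {
  x1 <- generate_colored_noise(2, 4096, 1000, seed = 42)
  x2 <- generate_colored_noise(2, 4096, 1000, seed = 42)
  expect_identical(x1, x2)
  expect_false(isTRUE(all.equal(x1, generate_colored_noise(2, 4096, 1000,
                                                           seed = 43))))
  expect_equal(mean(x1), 0, tolerance = 1e-12)
  expect_equal(sd(x1), 1, tolerance = 1e-12)
  expect_error(generate_colored_noise(2, 8), "at least 16")
  expect_error(generate_colored_noise(-1, 1024), "non-negative")
})

test_that("LFP generator embeds its ground truth", {
  p <- lfp_sim_params(duration_s = 60, theta_freq_hz = 8, seed = 5)
  sim <- generate_lfp(p)
  # ~8 cycles/s for 60 s, minus the boundary
  expect_true(length(sim$truth$cycle_times) %in% 479:480)
  expect_equal(sim$truth$true_beta, 2.5)
  # velocity exceeds 2 cm/s exactly while moving
  expect_true(all(sim$rec$velocity[sim$truth$moving_mask] > 2))
  # same seed reproduces bit-identically
  sim2 <- generate_lfp(p)
  expect_identical(sim$rec$lfp, sim2$rec$lfp)
})

test_that("LFP realizations differ by seed but share their variance scale", {
  v <- vapply(1:10, function(s) {
    var(generate_lfp(lfp_sim_params(duration_s = 20, seed = s))$rec$lfp)
  }, numeric(1))
  expect_true(all(abs(v - mean(v)) / mean(v) < 0.05))
})

test_that("movement bouts gate theta and the velocity trace", {
  bouts <- rbind(c(2, 6), c(10, 14))
  sim <- generate_lfp(lfp_sim_params(duration_s = 16, move_bouts = bouts,
                                     theta_freq_hz = 8, seed = 2))
  expect_true(all(sim$truth$cycle_times >= 2))
  tv <- (seq_along(sim$rec$velocity) - 1) / sim$rec$fs_vel_hz
  still <- tv >= 7 & tv < 9.5
  expect_true(all(sim$rec$velocity[still] <= 2))
  expect_true(all(vapply(sim$truth$cycle_times, function(ct) {
    any(ct >= bouts[, 1] & ct <= bouts[, 2])
  }, logical(1))))
})

test_that("out-of-band theta frequency warns but still generates", {
  expect_warning(
    sim <- generate_lfp(lfp_sim_params(duration_s = 10, theta_freq_hz = 4,
                                       seed = 1)),
    "outside the 5-12"
  )
  expect_length(sim$rec$lfp, 10000)
})

test_that("spine generator samples strictly inside each class region", {
  sp <- generate_spines(300, c(1, 0, 0), seed = 1)
  expect_true(all(sp$true_class == "stubby"))
  expect_true(all(classify_spines(sp) == "stubby"))
  expect_identical(nrow(generate_spines(0)), 0L)
  sp2 <- generate_spines(600, c(0.3, 0.3, 0.4), seed = 7)
  expect_false(any(sp2$length_um %in% c(1, 1.5)))
  expect_identical(classify_spines(sp2), sp2$true_class)
})

test_that("puncta image generator places the requested ground truth", {
  g <- generate_puncta_image(n_puncta = 10, noise_sd = 0, seed = 1)
  expect_identical(nrow(g$truth), 10L)
  # non-overlap: pairwise center distances exceed the radius sums
  d <- as.matrix(dist(g$truth[, c("x_um", "y_um")]))
  rs <- outer(g$truth$radius_um, g$truth$radius_um, `+`)
  expect_true(all(d[upper.tri(d)] > rs[upper.tri(rs)]))
  expect_true(all(g$truth$area_um2 >= 0.3 & g$truth$area_um2 <= 0.8))
  g0 <- generate_puncta_image(n_puncta = 0, seed = 1)
  expect_identical(nrow(g0$truth), 0L)
  expect_error(
    generate_puncta_image(field_um = c(3, 3), n_puncta = 500, seed = 1),
    "non-overlapping"
  )
})

test_that("recording CSV round-trips", {
  sim <- generate_lfp(lfp_sim_params(duration_s = 2, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(sim$rec, path)
  back <- read_recording_csv(path)
  expect_equal(back$lfp, sim$rec$lfp, tolerance = 1e-12)
  expect_equal(back$fs_hz, sim$rec$fs_hz)
})

test_that("SWC files round-trip through writer and reader", {
  tr <- generate_neuron_tree(3, step_um = 10, seed = 11)
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(tr, path)
  back <- read_swc(path)
  expect_equal(back$nodes$x, tr$nodes$x, tolerance = 1e-10)
  expect_identical(back$nodes$parent, tr$nodes$parent)
})

test_that("puncta TIFF round-trips with its sidecar", {
  g <- generate_puncta_image(n_puncta = 5, noise_sd = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".tif")
  write_puncta_tiff(g$img, path)
  back <- read_puncta_tiff(path)
  expect_equal(back$pixels, g$img$pixels)
  expect_equal(back$px_um, g$img$px_um)
})
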