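test_that("spine classification follows the published rule table", {
  expect_identical(classify_spine(0.8, neck_present = FALSE), "stubby")
  expect_identical(
    classify_spine(1.2, 0.6, 0.35, head_discernible = TRUE), "mushroom")
  expect_identical(classify_spine(1.7), "thin")
  expect_identical(classify_spine(1.2, head_discernible = FALSE), "thin")
  # boundary semantics: 1.5 um belongs to thin; head ratio inclusive
  expect_identical(classify_spine(1.5), "thin")
  expect_identical(
    classify_spine(1.0, 0.525, 0.35, head_discernible = TRUE), "mushroom")
  # no rule applies
  expect_message(
    out <- classify_spine(0.5, neck_present = TRUE, head_discernible = FALSE),
    "unclassified")
  expect_identical(out, "unclassified")
  expect_error(classify_spine(1, head_diam_um = 0.5,
                              head_discernible = FALSE), "head_discernible")
})

test_that("spine densities use half-open segments with a closed end", {
  sp <- data.frame(position_um = seq(5, 150, by = 5))
  d <- spine_density(sp)
  expect_equal(d$total_density, 0.2)
  expect_equal(d$segment$count, c(9, 10, 11))
  # position exactly 50 goes to the medial segment
  d2 <- spine_density(data.frame(position_um = 50))
  expect_equal(d2$segment$count, c(0, 1, 0))
  d0 <- spine_density(data.frame(position_um = numeric(0)))
  expect_true(all(d0$segment$density_per_um == 0))
  expect_message(spine_density(data.frame(position_um = c(10, 160))),
                 "excluded")
})

test_that("bouton detection applies both brightness and width criteria", {
  prof <- data.frame(position_um = seq(0, 10, by = 0.1),
                     brightness = 10, width_um = 0.2)
  prof$brightness[51] <- 25
  prof$width_um[51] <- 0.5
  b <- detect_boutons(prof)
  expect_identical(b$count, 1L)
  expect_equal(b$density_per_um, 0.1)
  expect_equal(b$backbone_brightness, 10)
  # brightness criterion fails at 1.5x
  prof$brightness[51] <- 15
  expect_identical(detect_boutons(prof)$count, 0L)
  # width criterion fails
  prof$brightness[51] <- 25
  prof$width_um[51] <- 0.3
  expect_identical(detect_boutons(prof)$count, 0L)
  # flat profile, manual crossing exclusion, short profile
  flat <- data.frame(position_um = seq(0, 12, by = 0.1),
                     brightness = 7, width_um = 0.2)
  expect_identical(detect_boutons(flat)$count, 0L)
  prof$width_um[51] <- 0.5
  prof$crossing <- FALSE
  prof$crossing[51] <- TRUE
  expect_identical(detect_boutons(prof)$count, 0L)
  expect_error(detect_boutons(prof[1:50, ]), "10 um")
})

test_that("Sholl analysis counts sphere crossings exactly", {
  cable <- generate_neuron_tree(0, step_um = 10, seed = 1)
  s <- sholl(cable, 20)
  expect_equal(s$intersections, rep(1L, 5))
  expect_identical(s$total, 5L)
  # bifurcation at 30 um, both branches radial to 70 um
  nodes <- data.frame(
    id = 1:7, type = c(1, rep(3, 6)),
    x = c(0, 15, 30, 50, 70, 50 * cos(0.4) , 70 * cos(0.4)),
    y = c(0, 0, 0, 0, 0, 50 * sin(0.4), 70 * sin(0.4)),
    z = 0, radius = 1, parent = c(-1, 1, 2, 3, 4, 3, 6))
  bi <- neuron_tree(nodes)
  sb <- sholl(bi, 20)
  expect_equal(sb$intersections, c(1L, 2L, 2L))
  expect_identical(sb$total, 5L)
})

test_that("Sholl agrees with the brute-force oracle on random trees", {
  for (s in 1:20) {
    tr <- generate_neuron_tree(s %% 7, step_um = 10, seed = s)
    expect_identical(as.integer(sholl(tr, 20)$intersections),
                     as.integer(sholl_brute_force(tr, 20)),
                     label = paste("tree seed", s))
  }
})

test_that("puncta counting recovers noiseless ground truth", {
  g <- generate_puncta_image(n_puncta = 10, noise_sd = 0, seed = 1)
  pc <- puncta_count(g$img, threshold = 100)
  expect_identical(pc$count, 10L)
  expect_equal(pc$density_per_um2, 10 / pc$roi_area_um2)
  # an area filter below the disk sizes removes everything
  pc0 <- puncta_count(g$img, threshold = 100, max_area_um2 = 0.1)
  expect_identical(pc0$count, 0L)
  g0 <- generate_puncta_image(n_puncta = 0, seed = 2)
  expect_identical(puncta_count(g0$img, threshold = 100)$count, 0L)
})

test_that("puncta counts are monotone non-increasing in the threshold", {
  # flat-top disks: raising the threshold can only remove objects
  # (pixel noise can fragment a disk near its intensity and break
  # monotonicity, so the property is checked on the noiseless image)
  g <- generate_puncta_image(n_puncta = 15, noise_sd = 0, seed = 5)
  counts <- vapply(c(40, 80, 120, 160, 200),
                   function(th) puncta_count(g$img, th)$count, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[1], 15L)
  expect_identical(counts[5], 0L)
})

test_that("E/I ratio is a guarded quotient", {
  expect_equal(ei_ratio(0.6, 0.3), 2)
  expect_equal(ei_ratio(0.3, 0.3), 1)
  expect_equal(ei_ratio(0, 0.3), 0)
  expect_error(ei_ratio(0.5, 0), "positive")
})

test_that("perisomatic ring density applies the area filter", {
  # 30x30 um field, square soma 10x10 in the middle
  px_um <- 0.1
  img <- matrix(20, 300, 300)
  soma <- data.frame(x = c(10, 20, 20, 10), y = c(10, 10, 20, 20))
  put_disk <- function(img, cx, cy, r_um) {
    xg <- (col(img) - 0.5) * px_um
    yg <- (row(img) - 0.5) * px_um
    img[(xg - cx)^2 + (yg - cy)^2 <= r_um^2] <- 220
    img
  }
  # 4 valid puncta (~0.5 um^2) inside the 1.25 um ring
  for (cxy in list(c(15, 9.4), c(15, 20.6), c(9.4, 15), c(20.6, 15))) {
    img <- put_disk(img, cxy[1], cxy[2], sqrt(0.5 / pi))
  }
  # one too small and one too large, also in the ring
  img <- put_disk(img, 12, 9.45, sqrt(0.05 / pi))
  img <- put_disk(img, 18.6, 18.6, 1.1)
  pim <- puncta_image(img, px_um)
  res <- perisomatic_density(pim, soma, threshold = 100)
  expect_identical(res$count, 4L)
  expect_equal(res$perimeter_um, 40)
  expect_equal(res$density_per_um, 0.1)
  expect_gt(res$area_fraction, 0)
  # ring exiting the field is an error
  soma_edge <- data.frame(x = c(0.2, 10, 10, 0.2), y = c(10, 10, 20, 20))
  expect_error(perisomatic_density(pim, soma_edge, threshold = 100),
               "exits")
})

test_that("optical density converts and normalizes grey levels", {
  px <- matrix(128, 10, 10)
  px[, 6:10] <- 255
  roi <- col(px) <= 5
  wm <- col(px) >= 6
  od <- optical_density(px, roi, wm)
  expect_equal(od$od, log10(255 / 128), tolerance = 1e-6)
  expect_equal(optical_density(matrix(77, 5, 5),
                               matrix(TRUE, 5, 5), matrix(TRUE, 5, 5))$od, 0)
  # darker ROI gives larger OD
  px2 <- px
  px2[roi] <- 64
  expect_gt(optical_density(px2, roi, wm)$od, od$od)
  # zero grey levels are clamped with a message
  px3 <- px
  px3[1, 1] <- 0
  expect_message(optical_density(px3, roi, wm), "clamped")
})

test_that("Cavalieri volumes are exact arithmetic", {
  expect_equal(cavalieri_volume(c(0.10, 0.12, 0.11), thickness = 0.05,
                                series_factor = 6), 0.099)
  expect_equal(cavalieri_volume(numeric(0)), 0)
  a <- c(0.2, 0.3)
  expect_equal(cavalieri_volume(2 * a), 2 * cavalieri_volume(a))
  expect_error(cavalieri_volume(c(0.1, -0.2)), "non-negative")
})

test_that("fractionator counts scale marker and co-localization totals", {
  cells <- c(rep(list("PV"), 6), rep(list("PNN"), 2),
             rep(list(c("PV", "PNN")), 4))
  fc <- fractionator_count(cells, c("PV", "PNN"))
  expect_equal(unname(fc$counts), c(60, 36))
  expect_equal(fc$co_counts["PV", "PNN"], 24)
  expect_lte(fc$co_counts["PV", "PNN"], min(fc$counts))
  f0 <- fractionator_count(list(), c("PV", "PNN"))
  expect_true(all(f0$counts == 0))
  expect_error(fractionator_count(list("GFAP"), c("PV", "PNN")), "unknown")
})

test_that("isotope ratios normalize positive to negative regions", {
  m <- data.frame(n15 = c(50, 40), n14 = c(10000, 10000),
                  label = c("positive", "negative"))
  expect_equal(isotope_ratio(m)$ratio, 1.25)
  m2 <- m
  m2$n15 <- c(40, 40)
  expect_equal(isotope_ratio(m2)$ratio, 1)
  m3 <- m
  m3$n15 <- m$n15 * 7
  m3$n14 <- m$n14 * 7
  expect_equal(isotope_ratio(m3)$ratio, 1.25)
  m4 <- m
  m4$n14[1] <- 0
  expect_error(isotope_ratio(m4), "positive")
  expect_error(isotope_ratio(m[1, ]), "negative ROI")
})

test_that("co-expression percentages count marker subsets", {
  cells <- c(rep(list(c("Gad1", "Epor")), 49), rep(list("Gad1"), 21))
  expect_equal(coexpression_percent(cells, "Gad1", "Epor"), 70)
  expect_equal(coexpression_percent(list("Gad1"), "Gad1", "Epor"), 0)
  expect_equal(coexpression_percent(list(c("Gad1", "Epor")), "Gad1", "Epor"),
               100)
  expect_error(coexpression_percent(list("Pvalb"), "Gad1", "Epor"),
               "base marker")
})

test_that("neuron tree validation rejects malformed structures", {
  good <- generate_neuron_tree(1, seed = 2)
  expect_s3_class(good, "neuron_tree")
  bad <- good$nodes
  bad$parent[1] <- 99
  expect_error(neuron_tree(bad), "root|reference")
  two_roots <- good$nodes
  two_roots$parent[2] <- -1
  expect_error(neuron_tree(two_roots), "exactly one root")
})
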