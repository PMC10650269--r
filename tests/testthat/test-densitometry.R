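test_that("peak detection finds clean Gaussians where they are", {
  prof <- gaussian_profile(0.5, 0.02, 10)
  pk <- detect_bands(prof, 1)
  expect_equal(pk$position, 0.5, tolerance = 1 / 511)

  prof2 <- gaussian_profile(c(0.3, 0.7), c(0.02, 0.02), c(5, 5))
  pk2 <- detect_bands(prof2, 2)
  expect_equal(pk2$position, c(0.3, 0.7), tolerance = 1 / 511)
  expect_true(all(diff(pk2$position) > 0))
})

test_that("asking for more bands than exist names the lane", {
  prof <- gaussian_profile(0.5, 0.02, 10, lane_id = "laneX")
  err <- expect_error(detect_bands(prof, 3),
                      class = "cpcrquant_error_band_shortfall")
  expect_match(conditionMessage(err), "laneX")
})

test_that("detected centres match generator truth within one sigma", {
  lane <- render_gel_lane(
    tibble::tibble(length_bp = c(296, 196), mass_ng = c(4, 2)),
    sim_config(seed = 14))
  truth <- band_truth(lane)
  pk <- detect_bands(lane, 2)
  expect_true(all(abs(pk$position - sort(truth$centre)) < truth$sigma[1]))
})

test_that("rubber-band baseline handles flat and offset profiles", {
  flat <- tibble::tibble(position = seq(0, 1, length.out = 101),
                         intensity = rep(7, 101))
  win <- subtract_baseline(flat, c(0.2, 0.8))
  expect_equal(attr(win, "baseline_area"), 7 * 0.6, tolerance = 1e-9)
  expect_equal(attr(win, "net_area"), 0, tolerance = 1e-12)

  # net intensity is invariant to adding any constant
  prof <- gaussian_profile(0.5, 0.03, 12)
  shifted <- dplyr::mutate(prof, intensity = intensity + 123.4)
  n1 <- attr(subtract_baseline(prof, c(0.35, 0.65)), "net_area")
  n2 <- attr(subtract_baseline(shifted, c(0.35, 0.65)), "net_area")
  expect_equal(n1, n2, tolerance = 1e-9)
})

test_that("a Gaussian integrates to its analytic area", {
  prof <- gaussian_profile(0.5, 0.03, 12)
  win <- subtract_baseline(prof, c(0.5 - 4 * 0.03, 0.5 + 4 * 0.03))
  expect_equal(attr(win, "net_area"), 12, tolerance = 0.01)
})

test_that("quantify_lane assigns bands by migration order and is linear", {
  cfg <- noiseless_cfg()
  assay <- methanogen_assay()
  equal <- render_gel_lane(
    tibble::tibble(name = c("target", "competitor"),
                   length_bp = c(296, 196), mass_ng = c(5, 5)), cfg)
  q <- quantify_lane(equal, assay)
  expect_equal(q$band, c("target", "competitor"))
  expect_equal(q$net_intensity[1], q$net_intensity[2], tolerance = 0.01)
  # target = earlier-migrating (smaller position)
  expect_lt(q$peak_position[1], q$peak_position[2])

  # rendering order does not matter: assignment is positional
  swapped <- render_gel_lane(
    tibble::tibble(name = c("competitor", "target"),
                   length_bp = c(196, 296), mass_ng = c(5, 5)), cfg)
  q2 <- quantify_lane(swapped, assay)
  expect_equal(q2$band, c("target", "competitor"))
  expect_equal(q2$peak_position, q$peak_position)

  # 10x mass -> 10x net intensity
  tenx <- render_gel_lane(
    tibble::tibble(name = c("target", "competitor"),
                   length_bp = c(296, 196), mass_ng = c(1, 10)), cfg)
  q3 <- quantify_lane(tenx, assay)
  expect_equal(q3$net_intensity[q3$band == "competitor"] /
                 q3$net_intensity[q3$band == "target"], 10,
               tolerance = 0.02)

  # doubling a mass doubles its band within 1%
  dbl <- render_gel_lane(
    tibble::tibble(name = c("target", "competitor"),
                   length_bp = c(296, 196), mass_ng = c(2, 10)), cfg)
  q4 <- quantify_lane(dbl, assay)
  expect_equal(q4$net_intensity[q4$band == "target"] /
                 q3$net_intensity[q3$band == "target"], 2,
               tolerance = 0.01)
})

test_that("generator areas are recovered within 2% across random lanes", {
  withr::with_seed(41, {
    rel_err <- replicate(30, {
      assay <- if (stats::runif(1) < 0.5) methanogen_assay() else protozoa_assay()
      masses <- 10^stats::runif(2, 0, 1.5)
      lane <- render_gel_lane(
        tibble::tibble(name = c("target", "competitor"),
                       length_bp = c(assay$target$length_bp,
                                     assay$competitor$length_bp),
                       mass_ng = masses),
        noiseless_cfg())
      truth <- band_truth(lane)
      q <- quantify_lane(lane, assay)
      max(abs(q$net_intensity / (truth$area[match(q$band, truth$name)]) - 1))
    })
    expect_lt(max(rel_err), 0.02)
  })
})
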