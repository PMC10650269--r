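test_that("blank correction subtracts blank means pointwise", {
  subs <- tibble::tibble(syringe_id = "s1", time_h = c(2, 4, 8),
                         volume_ml = c(10, 18, 30))
  zero_blank <- tibble::tibble(time_h = c(2, 4, 8), volume_ml = 0)
  expect_equal(assemble_curve(subs, zero_blank)$volume_ml, subs$volume_ml)

  const_blank <- tibble::tibble(time_h = rep(c(2, 4, 8), 2),
                                volume_ml = rep(5, 6))
  out <- assemble_curve(subs, const_blank)
  expect_equal(out$volume_ml, subs$volume_ml - 5)
  expect_true(all(out$blank_corrected))

  # blanks on a different grid are linearly interpolated
  off_grid <- tibble::tibble(time_h = c(1, 9), volume_ml = c(0, 8))
  out2 <- assemble_curve(subs, off_grid)
  expect_equal(out2$volume_ml, subs$volume_ml - c(1, 3, 7))
})

test_that("missing blanks error or pass through as configured", {
  subs <- tibble::tibble(time_h = c(2, 4, 8), volume_ml = c(10, 18, 30))
  expect_error(assemble_curve(subs, NULL),
               class = "cpcrquant_error_missing_blanks")
  out <- assemble_curve(subs, NULL, on_missing_blank = "passthrough")
  expect_false(any(out$blank_corrected))
  expect_equal(out$volume_ml, subs$volume_ml)
})

test_that("simulated blank drift is removed to within the noise level", {
  cfg <- sim_config(seed = 3, gas_noise_sd = 1)
  blank <- list(V = 8, k = 0.05)
  sub <- simulate_gas_curve(110, 0.09, cfg, blank = blank)
  blanks <- purrr::map(1:3, function(b) {
    simulate_gas_curve(NA, NA,
                       sim_config(seed = 100 + b, gas_noise_sd = 1),
                       syringe_id = paste0("b", b), blank = blank,
                       is_blank = TRUE)
  }) |> purrr::list_rbind()
  corrected <- assemble_curve(sub, blanks)
  truth <- gas_model(cfg$time_grid, 110, 0.09)
  # residual = own noise + mean blank noise: comfortably within 4 sd
  expect_lt(max(abs(corrected$volume_ml - truth)), 4 * 1 * sqrt(1 + 1 / 3))
})

test_that("noiseless curves are recovered to relative 1e-6", {
  curve <- simulate_gas_curve(100, 0.1, noiseless_cfg())
  fit <- fit_exponential(curve)
  expect_true(fit$converged)
  expect_equal(fit$V, 100, tolerance = 1e-6)
  expect_equal(fit$k, 0.1, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)

  fit2 <- fit_exponential(simulate_gas_curve(105.8, 0.0625, noiseless_cfg()))
  expect_equal(fit2$T0_5, log(2) / 0.0625, tolerance = 1e-6)  # 11.09 h
  expect_equal(fit2$G0_5, 52.9, tolerance = 1e-6)
})

test_that("the half-time identity y(T0.5) = G0.5 = V/2 holds exactly", {
  withr::with_seed(51, {
    for (i in 1:10) {
      curve <- simulate_gas_curve(stats::runif(1, 80, 150),
                                  stats::runif(1, 0.04, 0.12),
                                  sim_config(seed = 200 + i))
      fit <- fit_exponential(curve)
      expect_identical(fit$G0_5, fit$V / 2)
      expect_identical(fit$T0_5, log(2) / fit$k)
      expect_equal(gas_model(fit$T0_5, fit$V, fit$k), fit$G0_5,
                   tolerance = 1e-12)
    }
  })
})

test_that("volume scaling scales V and G0.5, leaves k and T0.5 alone", {
  curve <- simulate_gas_curve(120, 0.08, sim_config(seed = 6, gas_noise_sd = 2))
  f1 <- fit_exponential(curve)
  f2 <- fit_exponential(dplyr::mutate(curve, volume_ml = 3 * volume_ml))
  expect_equal(f2$V, 3 * f1$V, tolerance = 1e-6)
  expect_equal(f2$G0_5, 3 * f1$G0_5, tolerance = 1e-6)
  expect_equal(f2$k, f1$k, tolerance = 1e-6)
  expect_equal(f2$T0_5, f1$T0_5, tolerance = 1e-6)
})

test_that("NLS never loses to the coarse grid oracle", {
  withr::with_seed(52, {
    for (i in 1:10) {
      V <- stats::runif(1, 80, 150)
      k <- stats::runif(1, 0.04, 0.12)
      curve <- simulate_gas_curve(V, k, sim_config(seed = 300 + i,
                                                   gas_noise_sd = 2))
      fit <- fit_exponential(curve)
      oracle <- gas_grid_oracle(curve$time_h, curve$volume_ml)
      expect_lte(fit$rss, oracle + 1e-9)
    }
  })
})

test_that("noise-dominated data are flagged, degenerate inputs rejected", {
  junk <- tibble::tibble(time_h = c(2, 4, 8, 16, 32),
                         volume_ml = c(5, 4, 3, 2, 1))
  fit <- fit_exponential(junk)
  expect_false(fit$converged)
  expect_error(fit_exponential(junk[1:3, ]),
               class = "cpcrquant_error_insufficient_points")
  narrow <- tibble::tibble(time_h = c(10, 11, 12, 13),
                           volume_ml = c(1, 2, 3, 4))
  expect_error(fit_exponential(narrow), class = "cpcrquant_error_bad_input")
})

test_that("derived stats reproduce the published half-volume rows", {
  # printed asymptotic volumes: 124.2 (mid PSP), 141.2 (goat), 105.8 (camel)
  expect_equal(derived_stats(gas_kinetics_fit(124.2, 0.1))$G0_5_ml, 62.1)
  expect_equal(derived_stats(gas_kinetics_fit(141.2, 0.1))$G0_5_ml, 70.6)
  expect_equal(derived_stats(gas_kinetics_fit(105.8, 0.1))$G0_5_ml, 52.9)
  expect_equal(derived_stats(gas_kinetics_fit(100, log(2)))$T0_5_h, 1)
  ds <- derived_stats(gas_kinetics_fit(100, 0.1), times = c(0, 10))
  expect_equal(ds$predicted[[1]]$volume_ml, c(0, 100 * (1 - exp(-1))))
})

test_that("methane fraction is plain arithmetic with guard rails", {
  expect_equal(methane_fraction(0, 50), 0)
  expect_equal(methane_fraction(50, 50), 100)
  expect_equal(methane_fraction(9.94, 79.5), 12.5, tolerance = 0.01)
  expect_error(methane_fraction(60, 50), class = "cpcrquant_error_bad_input")
  expect_error(methane_fraction(1, 0), class = "cpcrquant_error_bad_input")
})

test_that("fit_gas_curves handles a long table with blanks", {
  cfg0 <- function(s) sim_config(seed = s, gas_noise_sd = 1)
  blank <- list(V = 6, k = 0.05)
  subs <- purrr::map(1:4, function(i) {
    simulate_gas_curve(100 + 5 * i, 0.08, cfg0(400 + i),
                       syringe_id = paste0("s", i), blank = blank)
  }) |> purrr::list_rbind()
  blanks <- purrr::map(1:3, function(b) {
    simulate_gas_curve(NA, NA, cfg0(500 + b),
                       syringe_id = paste0("b", b), blank = blank,
                       is_blank = TRUE)
  }) |> purrr::list_rbind()
  fits <- fit_gas_curves(dplyr::bind_rows(subs, blanks))
  expect_equal(nrow(fits), 4)
  expect_true(all(fits$converged))
  expect_equal(sort(fits$V), sort(100 + 5 * (1:4)), tolerance = 0.05)
})
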