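test_that("degradability is the disappeared fraction and scale-invariant", {
  expect_equal(degradability(500, 0), 1)
  expect_equal(degradability(500, 500), 0)
  expect_equal(degradability(500, 280), 0.44)
  withr::with_seed(61, {
    inn <- stats::runif(20, 100, 1000)
    res <- stats::runif(20, 0, 1) * inn
    expect_equal(degradability(3 * inn, 3 * res), degradability(inn, res))
  })
  expect_error(degradability(500, 501), class = "cpcrquant_error_bad_input")
  expect_error(degradability(0, 0), class = "cpcrquant_error_bad_input")
})

test_that("microbial protein subtracts the gas-bound substrate", {
  expect_equal(microbial_protein(400, 0), 400)
  expect_equal(microbial_protein(400, 100, 2.2), 180)
  expect_equal(microbial_protein(400, 100, 0), 400)
  expect_warning(out <- microbial_protein(10, 100, 2.2),
                 class = "cpcrquant_warning_mp_floored")
  expect_equal(out, 0)
})

test_that("group summaries report means, SEM and empty cells faithfully", {
  tr <- culture_truth(
    species_effects = list(goat = c(nh3_mg_dl = 0), camel = c(nh3_mg_dl = 0)),
    treatment_effects = list(`1` = c(), `2` = c(), `3` = c()),
    run_sd = c(nh3_mg_dl = 0), resid_sd = c(nh3_mg_dl = 0))
  d <- simulate_culture_dataset(tr, sim_config(seed = 62), n_per_cell = 2)
  gs <- group_summaries(d, "nh3_mg_dl", c("treatment", "species"))
  expect_equal(unique(gs$mean), unname(tr$mu[["nh3_mg_dl"]]),
               tolerance = 1e-12)
  expect_true(all(gs$sem[gs$n >= 2] == 0))

  # permuting rows changes nothing
  d2 <- d[sample(nrow(d)), ]
  expect_equal(group_summaries(d2, "ph", c("species")),
               group_summaries(d, "ph", c("species")))

  # an empty cell is reported with n = 0 and no mean
  d3 <- dplyr::filter(d, !(species == "camel" & treatment == "3"))
  gs3 <- group_summaries(d3, "ph", c("treatment", "species"))
  cell <- dplyr::filter(gs3, term == "treatment x species",
                        treatment == "3", species == "camel")
  expect_equal(cell$n, 0L)
  expect_true(is.na(cell$mean))
})

test_that("a balanced two-level shift is recovered within 3 SEM", {
  tr <- culture_truth(species_effects = list(
    goat = c(gas_ml = 7), camel = c(gas_ml = -7)))
  d <- simulate_culture_dataset(tr, sim_config(seed = 63), n_per_cell = 30)
  gs <- group_summaries(d, "gas_ml", "species")
  wide <- tidyr::pivot_wider(gs, names_from = "species",
                             values_from = c("mean", "sem"),
                             id_cols = "term")
  diff_hat <- wide$mean_goat - wide$mean_camel
  sem_diff <- sqrt(wide$sem_goat^2 + wide$sem_camel^2)
  expect_lt(abs(diff_hat - 14), 3 * sem_diff)
})

test_that("correlation endpoints, affine invariance and guards", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(population_correlation(x, x)$r, 1)
  expect_equal(population_correlation(x, -x)$r, -1)
  y <- c(2, 1, 4, 3, 6)
  r0 <- population_correlation(x, y)$r
  expect_equal(population_correlation(2.5 * x + 3, 0.1 * y - 7)$r, r0)
  expect_error(population_correlation(x, rep(1, 5)),
               class = "cpcrquant_error_undefined_correlation")
  expect_error(population_correlation(x[1:2], y[1:2]),
               class = "cpcrquant_error_insufficient_points")
})

test_that("the p-value matches the t-transform on n - 2 df", {
  withr::with_seed(64, {
    m <- stats::rnorm(20)
    p <- 0.5 * m + stats::rnorm(20)
    got <- population_correlation(m, p)
    r <- stats::cor(m, p)
    tstat <- r * sqrt(18 / (1 - r^2))
    expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), df = 18),
                 tolerance = 1e-12)
  })
})

test_that("simulated paired populations recover rho = 0.46 on average", {
  tr <- culture_truth(
    species_effects = list(goat = c(), camel = c()),
    treatment_effects = list(`1` = c(), `2` = c(), `3` = c()),
    run_sd = c(methanogen_log10 = 0, protozoa_log10 = 0))
  rs <- vapply(1:200, function(s) {
    d <- simulate_culture_dataset(tr, sim_config(seed = 1000 + s),
                                  times = c(12, 24, 48))
    population_correlation(d)$r  # n = 54 pairs
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.46), 0.05)
})
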