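# Shared fixtures: analytic profiles and a brute-force gas oracle.

# A lane profile holding Gaussian peaks on a known baseline.
gaussian_profile <- function(centres, sigmas, areas, baseline = 0,
                             n = 512, lane_id = "fix") {
  pos <- seq(0, 1, length.out = n)
  y <- rep(0, n)
  for (i in seq_along(centres)) {
    y <- y + areas[i] * stats::dnorm(pos, centres[i], sigmas[i])
  }
  if (length(baseline) == 1) baseline <- rep(baseline, n)
  tibble::tibble(lane_id = lane_id, position = pos,
                 intensity = y + baseline)
}

# Coarse grid-search oracle for the exponential gas model: best RSS on a
# 200 x 200 (V, k) lattice. Independent of the NLS path it checks.
gas_grid_oracle <- function(time_h, volume_ml,
                            V_range = c(0.5, 2) * max(volume_ml),
                            k_range = c(0.01, 0.5), n_grid = 200) {
  Vs <- seq(V_range[1], V_range[2], length.out = n_grid)
  ks <- seq(k_range[1], k_range[2], length.out = n_grid)
  best <- Inf
  for (k in ks) {
    m <- 1 - exp(-k * time_h)               # n_obs vector
    # RSS for all V at once: sum over obs of (y - V*m)^2
    rss <- vapply(Vs, function(V) sum((volume_ml - V * m)^2), numeric(1))
    best <- min(best, min(rss))
  }
  best
}

noiseless_cfg <- function(seed = NULL, ...) {
  sim_config(seed = seed, intensity_noise_cv = 0, profile_noise_sd = 0,
             gas_noise_sd = 0, ...)
}
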