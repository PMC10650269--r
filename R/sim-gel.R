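#' Render a synthetic 1-D gel lane profile
#'
#' Draws each DNA band as a Gaussian peak on a densitometer-style lane
#' profile spanning positions 0 to 1. Migration follows the standard agarose
#' approximation: peak centre is linear in -log10(length), so shorter
#' fragments sit farther along the lane. Peak area is proportional to dsDNA
#' mass (ethidium signal scales with base pairs, not molarity), multiplied
#' by lognormal noise with CV `cfg$intensity_noise_cv` (mean preserved).
#' A smooth positive baseline and additive white noise complete the lane.
#'
#' @param bands A data frame with columns `length_bp` and `mass_ng`
#'   (optionally `name`); one row per band, masses >= 0.
#' @param cfg A [sim_config()]; `peak_sigma`, `lane_gain`, `baseline_level`,
#'   `profile_noise_sd`, `intensity_noise_cv`, `profile_points` and `seed`
#'   are used.
#' @param lane_id Lane identifier carried into the output.
#' @return A tibble (`lane_id`, `position`, `intensity`) with attributes
#'   `band_truth` (tibble: `name`, `length_bp`, `centre`, `sigma`,
#'   `area_expected`, `area`) and `overlap` (`TRUE` if any two band centres
#'   lie within 3 sigma of each other; also raised as a warning). Retrieve
#'   the truth table with [band_truth()].
#' @export
#' @examples
#' lane <- render_gel_lane(
#'   tibble::tibble(length_bp = c(296, 196), mass_ng = c(5, 5)),
#'   sim_config(seed = 1)
#' )
render_gel_lane <- function(bands, cfg = sim_config(), lane_id = "lane1") {
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("length_bp", "mass_ng") %in% names(bands)))
  if (any(bands$mass_ng < 0)) {
    rlang::abort("Band masses must be >= 0.",
                 class = "cpcrquant_error_bad_input")
  }
  if (!"name" %in% names(bands)) {
    bands$name <- paste0("band", seq_len(nrow(bands)))
  }
  with_sim_seed(cfg, {
    pos <- seq(0, 1, length.out = cfg$profile_points)
    centre <- migration_position(bands$length_bp)
    sigma <- rep(cfg$peak_sigma, nrow(bands))

    area_expected <- bands$mass_ng * cfg$lane_gain
    noise <- lognormal_factor(nrow(bands), cfg$intensity_noise_cv)
    area <- area_expected * noise

    signal <- rep(0, length(pos))
    for (i in seq_len(nrow(bands))) {
      signal <- signal +
        area[i] * stats::dnorm(pos, mean = centre[i], sd = sigma[i])
    }
    # smooth positive baseline (linear, so an endpoint chord removes it
    # exactly) plus white detector noise
    baseline <- cfg$baseline_level * (1.2 - 0.4 * pos)
    intensity <- signal + baseline +
      stats::rnorm(length(pos), sd = cfg$profile_noise_sd)

    overlap <- FALSE
    if (nrow(bands) > 1) {
      d <- abs(outer(centre, centre, "-"))
      overlap <- any(d[upper.tri(d)] < 3 * cfg$peak_sigma)
      if (overlap) {
        rlang::warn(sprintf("Lane %s: band centres closer than 3 sigma (overlap).",
                            lane_id),
                    class = "cpcrquant_warning_band_overlap")
      }
    }

    out <- tibble::tibble(lane_id = lane_id, position = pos,
                          intensity = intensity)
    attr(out, "band_truth") <- tibble::tibble(
      name = bands$name, length_bp = bands$length_bp,
      centre = centre, sigma = sigma,
      area_expected = area_expected, area = area
    )
    attr(out, "overlap") <- overlap
    out
  })
}

#' @rdname render_gel_lane
#' @param profile A lane profile produced by [render_gel_lane()].
#' @export
band_truth <- function(profile) attr(profile, "band_truth")

# Pseudo-migration: centre linear in -log10(length), mapped so that a
# 100-1000 bp ladder spans positions 0.92 down to 0.08.
migration_position <- function(length_bp) {
  lo <- log10(100)
  hi <- log10(1000)
  frac <- (hi - log10(length_bp)) / (hi - lo)
  pmin(pmax(0.08 + 0.84 * frac, 0.02), 0.98)
}

# Mean-one multiplicative lognormal noise with the given CV.
lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
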