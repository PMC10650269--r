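#' Simulation configuration
#'
#' One bag of knobs shared by all synthetic-data generators. Every generator
#' is a pure function of its arguments plus `cfg`: fixing `seed` fixes the
#' output bit-for-bit, and `seed = NULL` draws from the session RNG stream.
#'
#' Defaults mirror the batch-culture protocol the package models: eleven
#' gas readings at 2, 4, 6, 8, 12, 24, 36, 48, 72, 96 and 120 h, ten-fold
#' competitor dilution series, and cycle counts taken from the assay
#' (34 for methanogens, 30 for protozoa) unless `pcr_cycles` overrides them.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param n_dilutions Number of points in a competitor dilution series.
#' @param dilution_base Fold-change per dilution step (> 1).
#' @param competitor_stock Competitor copies per reaction at the first
#'   (least dilute) point of a series.
#' @param pcr_cycles Optional cycle-count override; `NULL` uses the assay's.
#' @param pcr_efficiency Per-cycle amplification efficiency in (0, 1]
#'   (1 = perfect doubling).
#' @param plateau_total_copies Total product copies at which amplification
#'   saturates; both species are rescaled proportionally at the plateau so
#'   the molar ratio is preserved.
#' @param intensity_noise_cv Coefficient of variation of the multiplicative
#'   lognormal densitometry noise on band areas (>= 0).
#' @param gas_noise_sd Additive Gaussian noise on gas volumes, mL (>= 0).
#' @param time_grid Gas recording times in hours, strictly increasing, > 0.
#' @param profile_points Samples per rendered lane profile.
#' @param peak_sigma Gaussian band width (sd) in lane-position units
#'   (profiles span 0 to 1).
#' @param lane_gain Integrated intensity units per ng of DNA in a band.
#' @param baseline_level Scale of the smooth positive lane baseline.
#' @param profile_noise_sd Additive white noise on profile samples (>= 0).
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, intensity_noise_cv = 0.1)
sim_config <- function(seed = NULL,
                       n_dilutions = 11,
                       dilution_base = 10,
                       competitor_stock = 1e9,
                       pcr_cycles = NULL,
                       pcr_efficiency = 0.85,
                       plateau_total_copies = 1e12,
                       intensity_noise_cv = 0.1,
                       gas_noise_sd = 2,
                       time_grid = c(2, 4, 6, 8, 12, 24, 36, 48, 72, 96, 120),
                       profile_points = 512,
                       peak_sigma = 0.015,
                       lane_gain = 100,
                       baseline_level = 2,
                       profile_noise_sd = 0.5) {
  bad <- function(msg) rlang::abort(msg, class = "cpcrquant_error_bad_config")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) bad("`seed` must be an integer or NULL.")
  }
  if (n_dilutions < 1) bad("`n_dilutions` must be >= 1.")
  if (dilution_base <= 1) bad("`dilution_base` must be > 1.")
  if (competitor_stock <= 0) bad("`competitor_stock` must be > 0.")
  if (pcr_efficiency <= 0 || pcr_efficiency > 1) {
    bad("`pcr_efficiency` must be in (0, 1].")
  }
  if (plateau_total_copies <= 0) bad("`plateau_total_copies` must be > 0.")
  if (intensity_noise_cv < 0 || gas_noise_sd < 0 || profile_noise_sd < 0) {
    bad("Noise parameters must be >= 0.")
  }
  if (any(diff(time_grid) <= 0) || any(time_grid <= 0)) {
    bad("`time_grid` must be strictly increasing and > 0.")
  }
  structure(
    list(
      seed = seed,
      n_dilutions = as.integer(n_dilutions),
      dilution_base = dilution_base,
      competitor_stock = competitor_stock,
      pcr_cycles = if (is.null(pcr_cycles)) NULL else as.integer(pcr_cycles),
      pcr_efficiency = pcr_efficiency,
      plateau_total_copies = plateau_total_copies,
      intensity_noise_cv = intensity_noise_cv,
      gas_noise_sd = gas_noise_sd,
      time_grid = as.numeric(time_grid),
      profile_points = as.integer(profile_points),
      peak_sigma = peak_sigma,
      lane_gain = lane_gain,
      baseline_level = baseline_level,
      profile_noise_sd = profile_noise_sd
    ),
    class = "sim_config"
  )
}

# Run `code` under cfg$seed without disturbing the caller's RNG stream;
# with a NULL seed the current stream is used (impure on purpose).
with_sim_seed <- function(cfg, code) {
  if (is.null(cfg$seed)) force(code) else withr::with_seed(cfg$seed, code)
}

# Deterministic child seed, kept inside 32-bit integer range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}
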