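#' Ground truth for the factorial culture simulator
#'
#' Collects the cell means and effects that [simulate_culture_dataset()]
#' injects. Defaults emulate a 2 species (goat, camel) x 3 diets x 3 runs
#' batch-culture study: goats carry higher NH3-N, total VFA, gas and
#' microbial populations, camels higher pH and microbial protein, and the
#' two log10 populations share a residual correlation of 0.46 (methanogens
#' ride along with their protozoal hosts).
#'
#' @param mu Named vector of overall means. Responses: `ph`, `nh3_mg_dl`,
#'   `mp_mg_ml`, `vfa_mm_ml`, `acetate_mm_ml`, `propionate_mm_ml`,
#'   `butyrate_mm_ml`, `ddm`, `ndfd`, `gas_ml`, `methanogen_log10`,
#'   `protozoa_log10` (`ddm`/`ndfd` are degradable fractions, later turned
#'   into residue masses).
#' @param species_effects,treatment_effects Named lists (by level) of named
#'   numeric vectors of mean shifts; unnamed responses default to 0.
#' @param run_sd,resid_sd Named vectors of the random run-effect and
#'   residual standard deviations (missing responses default to 0).
#' @param pop_rho Residual correlation between the two log10 populations.
#' @return A list of class `culture_truth`.
#' @export
culture_truth <- function(mu = NULL, species_effects = NULL,
                          treatment_effects = NULL,
                          run_sd = NULL, resid_sd = NULL, pop_rho = 0.46) {
  def_mu <- c(ph = 6.4, nh3_mg_dl = 30.9, mp_mg_ml = 134.5, vfa_mm_ml = 2.2,
              acetate_mm_ml = 0.47, propionate_mm_ml = 0.2,
              butyrate_mm_ml = 0.33, ddm = 0.28, ndfd = 0.44, gas_ml = 93,
              methanogen_log10 = 4.95, protozoa_log10 = 5.05)
  def_species <- list(
    goat = c(ph = -0.2, nh3_mg_dl = 8.2, mp_mg_ml = -22.4, vfa_mm_ml = 0.3,
             gas_ml = 13.6, methanogen_log10 = 0.35, protozoa_log10 = 0.35),
    camel = c(ph = 0.2, nh3_mg_dl = -8.2, mp_mg_ml = 22.4, vfa_mm_ml = -0.3,
              gas_ml = -13.6, methanogen_log10 = -0.35,
              protozoa_log10 = -0.35)
  )
  def_treat <- list(
    `1` = c(nh3_mg_dl = -1.1, mp_mg_ml = -13.5, gas_ml = 1.5),
    `2` = c(nh3_mg_dl = -0.4, mp_mg_ml = -8.5, ndfd = 0.04, gas_ml = 1),
    `3` = c(nh3_mg_dl = 1.5, mp_mg_ml = 22, ndfd = -0.04, gas_ml = -2.5)
  )
  def_run_sd <- c(ph = 0.05, nh3_mg_dl = 1, mp_mg_ml = 8, vfa_mm_ml = 0.05,
                  acetate_mm_ml = 0.02, propionate_mm_ml = 0.01,
                  butyrate_mm_ml = 0.02, ddm = 0.01, ndfd = 0.02,
                  gas_ml = 2, methanogen_log10 = 0.1, protozoa_log10 = 0.1)
  def_resid_sd <- c(ph = 0.15, nh3_mg_dl = 2.5, mp_mg_ml = 20,
                    vfa_mm_ml = 0.12, acetate_mm_ml = 0.08,
                    propionate_mm_ml = 0.04, butyrate_mm_ml = 0.05,
                    ddm = 0.02, ndfd = 0.05, gas_ml = 4,
                    methanogen_log10 = 0.35, protozoa_log10 = 0.35)
  merge_named <- function(def, user) {
    if (is.null(user)) return(def)
    def[names(user)] <- user
    def
  }
  structure(
    list(
      mu = merge_named(def_mu, mu),
      species_effects = if (is.null(species_effects)) def_species else species_effects,
      treatment_effects = if (is.null(treatment_effects)) def_treat else treatment_effects,
      run_sd = merge_named(def_run_sd, run_sd),
      resid_sd = merge_named(def_resid_sd, resid_sd),
      pop_rho = pop_rho
    ),
    class = "culture_truth"
  )
}

#' Simulate a factorial batch-culture dataset
#'
#' Each record is `mu + treatment effect + species effect + run effect
#' (random, shared within a run) + residual`, per response. The two log10
#' population responses get correlated residuals (`truth$pop_rho`).
#' Degradable fractions are converted to residue masses around a nominal
#' 500 mg DM substrate load (uniform +/- 10 mg weighing jitter) with NDF
#' taken as 48% of substrate.
#'
#' @param truth A [culture_truth()].
#' @param cfg A [sim_config()]; only `seed` is used.
#' @param species,treatments,runs Factor levels of the design.
#' @param times Sampling times (h); effects are time-constant.
#' @param n_per_cell Replicate records per design cell and time.
#' @return A tibble with one row per record: design columns (`species`,
#'   `treatment`, `run`, `time_h`, `replicate`), measured responses, and
#'   mass columns `substrate_in_mg`, `residue_mg`, `ndf_in_mg`,
#'   `ndf_residue_mg`.
#' @export
#' @examples
#' simulate_culture_dataset(culture_truth(), sim_config(seed = 42))
simulate_culture_dataset <- function(truth = culture_truth(),
                                     cfg = sim_config(),
                                     species = c("goat", "camel"),
                                     treatments = c("1", "2", "3"),
                                     runs = c("1", "2", "3"),
                                     times = 24, n_per_cell = 1) {
  responses <- names(truth$mu)
  with_sim_seed(cfg, {
    design <- tidyr::expand_grid(
      species = species, treatment = treatments, run = runs,
      time_h = times, replicate = seq_len(n_per_cell)
    )
    n <- nrow(design)

    named_or <- function(v, key, default = 0) {
      x <- unname(v[key])
      if (length(x) == 0 || is.na(x)) default else x
    }

    # run effects: one draw per run per response, shared within the run
    run_fx <- matrix(0, nrow = length(runs), ncol = length(responses),
                     dimnames = list(runs, responses))
    for (r in responses) {
      run_fx[, r] <- stats::rnorm(length(runs),
                                  sd = named_or(truth$run_sd, r))
    }

    eff <- function(tbl, level, resp) {
      v <- tbl[[level]]
      if (is.null(v)) 0 else named_or(v, resp)
    }

    vals <- matrix(0, nrow = n, ncol = length(responses),
                   dimnames = list(NULL, responses))
    # correlated residuals for the paired populations
    rho <- truth$pop_rho
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    pop_resid <- cbind(
      methanogen_log10 = named_or(truth$resid_sd, "methanogen_log10") * z1,
      protozoa_log10 = named_or(truth$resid_sd, "protozoa_log10") *
        (rho * z1 + sqrt(1 - rho^2) * z2)
    )
    for (r in responses) {
      resid <- if (r %in% colnames(pop_resid)) {
        pop_resid[, r]
      } else {
        stats::rnorm(n, sd = named_or(truth$resid_sd, r))
      }
      vals[, r] <- truth$mu[[r]] +
        purrr::map_dbl(design$species, ~ eff(truth$species_effects, .x, r)) +
        purrr::map_dbl(design$treatment, ~ eff(truth$treatment_effects, .x, r)) +
        run_fx[design$run, r] +
        resid
    }

    out <- dplyr::bind_cols(design, tibble::as_tibble(vals))
    out$ddm <- pmin(pmax(out$ddm, 0.01), 0.99)
    out$ndfd <- pmin(pmax(out$ndfd, 0.01), 0.99)
    out$substrate_in_mg <- 500 + stats::runif(n, -10, 10)
    out$residue_mg <- out$substrate_in_mg * (1 - out$ddm)
    out$ndf_in_mg <- out$substrate_in_mg * 0.48
    out$ndf_residue_mg <- out$ndf_in_mg * (1 - out$ndfd)
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
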