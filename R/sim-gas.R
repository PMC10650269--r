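#' Simulate a cumulative gas-production curve
#'
#' Evaluates the exponential model without lag, `y(t) = V (1 - exp(-k t))`,
#' on `cfg$time_grid` and adds Gaussian reading noise with sd
#' `cfg$gas_noise_sd`. Noisy values are kept as read (no monotonicity
#' clipping) — early readings may dip, exactly as transducer logs do. An
#' optional blank drift `b(t) = Vb (1 - exp(-kb t))` models the gas produced
#' by buffered rumen fluid alone; substrate syringes receive truth + drift,
#' blank syringes drift only.
#'
#' @param true_V Asymptotic gas volume, mL (> 0).
#' @param true_k Fractional rate, per hour (> 0).
#' @param cfg A [sim_config()]; `time_grid`, `gas_noise_sd`, `seed`.
#' @param syringe_id Identifier carried into the output.
#' @param blank `NULL` for no drift, or `list(V = , k = )` for the blank
#'   channel added to the readings.
#' @param is_blank If `TRUE`, the syringe contains no substrate and only the
#'   blank drift (plus noise) is recorded; `blank` must then be supplied.
#' @return A tibble (`syringe_id`, `is_blank`, `time_h`, `volume_ml`) with
#'   attribute `truth = list(true_V, true_k, blank)`.
#' @export
#' @examples
#' simulate_gas_curve(100, 0.1, sim_config(seed = 3, gas_noise_sd = 0))
simulate_gas_curve <- function(true_V, true_k, cfg = sim_config(),
                               syringe_id = "syr1", blank = NULL,
                               is_blank = FALSE) {
  if (!is_blank && (true_V <= 0 || true_k <= 0)) {
    rlang::abort("`true_V` and `true_k` must be > 0.",
                 class = "cpcrquant_error_bad_input")
  }
  if (is_blank && is.null(blank)) {
    rlang::abort("A blank syringe needs a `blank = list(V, k)` drift model.",
                 class = "cpcrquant_error_bad_input")
  }
  with_sim_seed(cfg, {
    t <- cfg$time_grid
    y <- if (is_blank) rep(0, length(t)) else gas_model(t, true_V, true_k)
    if (!is.null(blank)) y <- y + gas_model(t, blank$V, blank$k)
    y <- y + stats::rnorm(length(t), sd = cfg$gas_noise_sd)
    out <- tibble::tibble(syringe_id = syringe_id, is_blank = is_blank,
                          time_h = t, volume_ml = y)
    attr(out, "truth") <- list(true_V = true_V, true_k = true_k,
                               blank = blank)
    out
  })
}

#' Exponential gas model without lag
#'
#' @param t Time, hours.
#' @param V Asymptotic volume, mL.
#' @param k Fractional rate, per hour.
#' @return `V * (1 - exp(-k * t))`, vectorized over `t`.
#' @export
gas_model <- function(t, V, k) V * (1 - exp(-k * t))
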