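#' Simulate a competitor dilution series
#'
#' Emulates the bench titration: a fixed amount of target template is
#' co-amplified against a competitor diluted `dilution_base`-fold per step
#' from `cfg$competitor_stock`, each reaction is run through
#' [simulate_competitive_pcr()] and the products are rendered as a gel lane
#' with [render_gel_lane()]. Both the band-intensity table (the noisy band
#' areas a perfect densitometry step would read) and the raw lane profiles
#' are returned, together with the ground truth.
#'
#' @param true_target_copies Target template copies per reaction (> 0).
#' @param assay A [assay_spec()].
#' @param cfg A [sim_config()] (`n_dilutions` must be >= 3). With a non-NULL
#'   `seed` the whole series is reproducible bit-for-bit.
#' @return A list of class `cpcr_series`:
#'   * `points` — tibble (`lane_id`, `dilution_step`, `competitor_copies`,
#'     `target_intensity`, `competitor_intensity`, `usable`), the
#'     [build_calibration()] input;
#'   * `profiles` — tibble (`lane_id`, `position`, `intensity`) stacking all
#'     lanes;
#'   * `truth` — list with `true_target_copies`, the assay and the config.
#' @export
#' @examples
#' ser <- simulate_dilution_series(1e5, methanogen_assay(),
#'                                 sim_config(seed = 7, n_dilutions = 8))
#' ser$points
simulate_dilution_series <- function(true_target_copies,
                                     assay = methanogen_assay(),
                                     cfg = sim_config()) {
  if (true_target_copies <= 0) {
    rlang::abort("`true_target_copies` must be > 0.",
                 class = "cpcrquant_error_bad_input")
  }
  if (cfg$n_dilutions < 3) {
    rlang::abort("A dilution series needs `n_dilutions` >= 3.",
                 class = "cpcrquant_error_bad_config")
  }
  steps <- seq_len(cfg$n_dilutions)
  competitor_copies <- cfg$competitor_stock / cfg$dilution_base^(steps - 1)

  lanes <- purrr::map(steps, function(i) {
    rx <- simulate_competitive_pcr(true_target_copies, competitor_copies[i],
                                   assay, cfg)
    lane_cfg <- cfg
    lane_cfg$seed <- child_seed(cfg$seed, i)
    profile <- render_gel_lane(
      tibble::tibble(name = rx$fragment, length_bp = rx$length_bp,
                     mass_ng = rx$mass_ng),
      lane_cfg,
      lane_id = sprintf("%s_d%02d", assay$taxon, i)
    )
    truth <- band_truth(profile)
    list(
      point = tibble::tibble(
        lane_id = profile$lane_id[1],
        dilution_step = i,
        competitor_copies = competitor_copies[i],
        target_intensity = truth$area[truth$name == "target"],
        competitor_intensity = truth$area[truth$name == "competitor"]
      ),
      profile = profile
    )
  })

  points <- purrr::list_rbind(purrr::map(lanes, "point"))
  points$usable <- points$target_intensity > 0 & points$competitor_intensity > 0

  structure(
    list(
      points = points,
      profiles = purrr::list_rbind(purrr::map(lanes, "profile")),
      truth = list(true_target_copies = true_target_copies,
                   assay = assay, cfg = cfg)
    ),
    class = "cpcr_series"
  )
}

#' @export
print.cpcr_series <- function(x, ...) {
  cat(sprintf("<cpcr_series> %s assay, %d dilutions, true target %.3g copies/reaction\n",
              x$truth$assay$taxon, nrow(x$points),
              x$truth$true_target_copies))
  print(x$points, ...)
  invisible(x)
}
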