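#' Convert an equivalence point to copies per mL of culture fluid
#'
#' `copies/mL = equivalence_copies / template_volume_ml * prod(dilution_chain)`.
#' The chain of fold-factors between culture fluid and the PCR template
#' (extraction volume ratios, extract dilutions, ...) is mandatory,
#' explicit configuration — pass `c(extract = 1)` for a direct 1:1 chain;
#' there is no silent default. Every factor is recorded in the estimate's
#' provenance.
#'
#' @param fit A `cpcr_calibration` from [build_calibration()], or a bare
#'   positive number of copies per reaction.
#' @param template_volume_ml Volume of template entering one reaction, mL
#'   (> 0); 1 uL is 0.001.
#' @param dilution_chain Named or unnamed numeric vector of fold factors
#'   (> 0) multiplying reaction-volume concentration up to culture-fluid
#'   concentration.
#' @param taxon Population label carried into the output.
#' @return A one-row tibble (`taxon`, `equivalence_copies`,
#'   `copies_per_ml`, `log10_copies_per_ml`, `slope`, `r_squared`,
#'   `extrapolated`, `provenance`); `provenance` is a list-column holding a
#'   tibble of every multiplicative factor applied.
#' @export
#' @examples
#' copies_per_ml(1e5, template_volume_ml = 0.001,
#'               dilution_chain = c(extract = 1), taxon = "methanogen")
copies_per_ml <- function(fit, template_volume_ml, dilution_chain,
                          taxon = NA_character_) {
  if (missing(dilution_chain) || is.null(dilution_chain) ||
      length(dilution_chain) == 0) {
    rlang::abort(
      "An explicit `dilution_chain` is required (use c(extract = 1) for a unit chain).",
      class = "cpcrquant_error_missing_chain")
  }
  if (any(dilution_chain <= 0) || template_volume_ml <= 0) {
    rlang::abort("`template_volume_ml` and all chain factors must be > 0.",
                 class = "cpcrquant_error_bad_input")
  }
  is_cal <- inherits(fit, "cpcr_calibration")
  eq <- if (is_cal) fit$equivalence_copies else as.numeric(fit)
  if (!is.finite(eq) || eq <= 0) {
    rlang::abort("Equivalence copies must be finite and > 0.",
                 class = "cpcrquant_error_bad_input")
  }
  per_ml <- eq / template_volume_ml * prod(dilution_chain)
  chain_names <- names(dilution_chain) %||%
    paste0("factor", seq_along(dilution_chain))
  chain_names[chain_names == ""] <-
    paste0("factor", seq_along(dilution_chain))[chain_names == ""]
  provenance <- tibble::tibble(
    step = c("per_reaction_to_per_ml_template", chain_names),
    factor = c(1 / template_volume_ml, unname(dilution_chain))
  )
  tibble::tibble(
    taxon = taxon,
    equivalence_copies = eq,
    copies_per_ml = per_ml,
    log10_copies_per_ml = log10(per_ml),
    slope = if (is_cal) fit$slope else NA_real_,
    r_squared = if (is_cal) fit$r_squared else NA_real_,
    extrapolated = if (is_cal) fit$extrapolated else NA,
    provenance = list(provenance)
  )
}

#' Enumerate a microbial population from a dilution series
#'
#' Full composition of the quantification path: densitometry (when raw lane
#' profiles are supplied) -> calibration ([build_calibration()]) ->
#' [copies_per_ml()]. Lanes whose bands cannot both be detected (one
#' product far below the other, as at the extreme ends of a titration) are
#' marked unusable and dropped rather than failing the run.
#'
#' @param x Either a lane-profile tibble (`lane_id`, `position`,
#'   `intensity`) to be quantified with [quantify_lane()], or a
#'   band-intensity tibble already holding `target_intensity` and
#'   `competitor_intensity` per `lane_id`.
#' @param series_meta A tibble (`lane_id`, `competitor_copies`) mapping each
#'   lane to the competitor copies loaded into its reaction.
#' @param assay The [assay_spec()].
#' @param template_volume_ml,dilution_chain Passed to [copies_per_ml()].
#' @param mode Calibration mode, see [build_calibration()]; default
#'   `"molar"` (unbiased equivalence).
#' @param ... Passed to [quantify_lane()].
#' @return A list of class `cpcr_enumeration`: `estimate` (the
#'   [copies_per_ml()] tibble), `calibration` (the `cpcr_calibration`),
#'   and `intensities` (per-lane band table with `usable` flags).
#' @export
enumerate_population <- function(x, series_meta, assay,
                                 template_volume_ml, dilution_chain,
                                 mode = c("molar", "raw"), ...) {
  mode <- rlang::arg_match(mode)
  x <- tibble::as_tibble(x)
  stopifnot(all(c("lane_id", "competitor_copies") %in% names(series_meta)))

  if (all(c("target_intensity", "competitor_intensity") %in% names(x))) {
    intens <- dplyr::select(x, "lane_id", "target_intensity",
                            "competitor_intensity", dplyr::any_of("usable"))
  } else {
    stopifnot(all(c("lane_id", "position", "intensity") %in% names(x)))
    intens <- x |>
      dplyr::group_by(.data$lane_id) |>
      dplyr::group_map(function(prof, key) {
        prof$lane_id <- key$lane_id
        check_profile(prof)
        m <- tryCatch(quantify_lane(prof, assay, ...),
                      cpcrquant_error_band_shortfall = function(e) NULL)
        if (is.null(m)) {
          return(tibble::tibble(lane_id = key$lane_id,
                                target_intensity = NA_real_,
                                competitor_intensity = NA_real_,
                                usable = FALSE))
        }
        tibble::tibble(
          lane_id = key$lane_id,
          target_intensity = m$net_intensity[m$band == "target"],
          competitor_intensity = m$net_intensity[m$band == "competitor"],
          usable = !any(m$clamped)
        )
      }) |>
      purrr::list_rbind()
  }
  if (!"usable" %in% names(intens)) intens$usable <- TRUE
  intens$usable <- intens$usable &
    !is.na(intens$target_intensity) & !is.na(intens$competitor_intensity)

  pts <- dplyr::inner_join(intens, series_meta, by = "lane_id")
  cal <- build_calibration(pts, mode = mode, assay = assay)
  est <- copies_per_ml(cal, template_volume_ml, dilution_chain,
                       taxon = assay$taxon)
  structure(list(estimate = est, calibration = cal, intensities = intens),
            class = "cpcr_enumeration")
}

#' @export
print.cpcr_enumeration <- function(x, ...) {
  cat(sprintf("<cpcr_enumeration> %s: %.3f log10 copies/mL (%d/%d lanes usable)\n",
              x$estimate$taxon, x$estimate$log10_copies_per_ml,
              sum(x$intensities$usable), nrow(x$intensities)))
  print(x$calibration)
  invisible(x)
}
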