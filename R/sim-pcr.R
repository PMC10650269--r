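#' Simulate one competitive co-amplification
#'
#' Both templates (the genomic target and the shorter competitor sharing its
#' primers) amplify with the same per-cycle efficiency `e` for `c` cycles,
#' `N' = N * (1 + e)^c`. If the summed product exceeds
#' `cfg$plateau_total_copies`, both products are rescaled by a common factor
#' so the sum equals the plateau. Either way the molar product ratio equals
#' the initial template ratio exactly — the property that makes competitive
#' PCR a valid titration. Product masses follow from fragment length via
#' [mass_from_copies()].
#'
#' @param target_copies,competitor_copies Template copies per reaction (>= 0).
#' @param assay A [assay_spec()] giving fragment lengths and cycle count.
#' @param cfg A [sim_config()]; `pcr_efficiency`, `plateau_total_copies` and
#'   the optional `pcr_cycles` override are used. No randomness is involved.
#' @return A two-row tibble (`fragment`, `length_bp`, `copies_in`,
#'   `copies_out`, `mass_ng`) with rows `target`, `competitor`.
#' @export
#' @examples
#' simulate_competitive_pcr(1e5, 1e4, methanogen_assay(), sim_config())
simulate_competitive_pcr <- function(target_copies, competitor_copies,
                                     assay = methanogen_assay(),
                                     cfg = sim_config()) {
  if (target_copies < 0 || competitor_copies < 0) {
    rlang::abort("Template copy numbers must be >= 0.",
                 class = "cpcrquant_error_bad_input")
  }
  cycles <- if (is.null(cfg$pcr_cycles)) assay$cycles else cfg$pcr_cycles
  n_in <- c(target = target_copies, competitor = competitor_copies)
  n_out <- n_in * (1 + cfg$pcr_efficiency)^cycles
  total <- sum(n_out)
  if (total > cfg$plateau_total_copies) {
    n_out <- n_out * cfg$plateau_total_copies / total
  }
  lengths <- c(assay$target$length_bp, assay$competitor$length_bp)
  tibble::tibble(
    fragment = c("target", "competitor"),
    length_bp = lengths,
    copies_in = unname(n_in),
    copies_out = unname(n_out),
    mass_ng = mass_from_copies(unname(n_out), lengths)
  )
}
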