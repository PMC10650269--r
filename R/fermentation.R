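#' Substrate degradability from residue mass
#'
#' Fraction of the incubated substrate that disappeared:
#' `(in - residue) / in`. The same operation serves dry-matter
#' degradability (DDM) and NDF degradability (NDFD) given the matching
#' input/residue masses. Scale-invariant: `(c*in, c*residue)` gives the
#' same fraction.
#'
#' @param substrate_in_mg Mass incubated, mg (> 0); vectorized.
#' @param residue_mg Mass recovered after incubation, mg
#'   (0 <= residue <= in).
#' @return Degraded fraction in \[0, 1\].
#' @export
#' @examples
#' degradability(500, 280)  # 0.44
degradability <- function(substrate_in_mg, residue_mg) {
  if (any(substrate_in_mg <= 0)) {
    rlang::abort("`substrate_in_mg` must be > 0.",
                 class = "cpcrquant_error_bad_input")
  }
  if (any(residue_mg < 0) || any(residue_mg > substrate_in_mg)) {
    rlang::abort("`residue_mg` must lie in [0, substrate_in_mg].",
                 class = "cpcrquant_error_bad_input")
  }
  (substrate_in_mg - residue_mg) / substrate_in_mg
}

#' Microbial protein from truly degraded substrate and gas
#'
#' Partitioning estimate: substrate truly degraded minus the part accounted
#' for by fermentation gas, `MP = degraded - gas * stoich_factor`. The
#' stoichiometric factor (mg degraded substrate per mL of gas) is explicit
#' configuration with a conventional default of 2.2. Negative estimates are
#' floored at zero with a warning (they indicate an inconsistent
#' gas/degradability pairing, not biology).
#'
#' @param truly_degraded_mg Truly degraded substrate, mg (>= 0); vectorized.
#' @param gas_ml Cumulative gas, mL (>= 0).
#' @param stoich_factor mg substrate per mL gas (>= 0).
#' @return Microbial protein estimate, mg.
#' @export
#' @examples
#' microbial_protein(400, 100)  # 180
microbial_protein <- function(truly_degraded_mg, gas_ml, stoich_factor = 2.2) {
  if (any(truly_degraded_mg < 0) || any(gas_ml < 0) || stoich_factor < 0) {
    rlang::abort("Inputs must be >= 0.", class = "cpcrquant_error_bad_input")
  }
  mp <- truly_degraded_mg - gas_ml * stoich_factor
  if (any(mp < 0)) {
    rlang::warn(sprintf("%d microbial-protein estimate(s) < 0 floored at 0.",
                        sum(mp < 0)),
                class = "cpcrquant_warning_mp_floored")
    mp <- pmax(mp, 0)
  }
  mp
}

#' Mean and SEM summaries over design factors
#'
#' The mean +/- SEM bookkeeping behind a factorial results table: one
#' summary block per single factor plus one for the full interaction.
#' SEM = sd / sqrt(n), reported for cells with n >= 2; empty cells appear
#' with n = 0 and no mean. Output rows follow the declared factor-level
#' order (the column's factor levels, or order of first appearance).
#'
#' @param records A data frame of culture records.
#' @param response Name of the numeric response column.
#' @param factors Character vector of grouping columns, e.g.
#'   `c("treatment", "species")`.
#' @return A tibble (`term`, one column per factor (NA where not part of
#'   the term), `n`, `mean`, `sem`).
#' @export
#' @examples
#' recs <- simulate_culture_dataset(cfg = sim_config(seed = 5))
#' group_summaries(recs, "nh3_mg_dl", c("treatment", "species"))
group_summaries <- function(records, response, factors) {
  records <- tibble::as_tibble(records)
  stopifnot(response %in% names(records), all(factors %in% names(records)))
  lvls <- purrr::map(rlang::set_names(factors), function(f) {
    v <- records[[f]]
    if (is.factor(v)) levels(v) else sort(unique(as.character(v)))
  })
  summarise_by <- function(by) {
    grid <- tidyr::expand_grid(!!!lvls[by])
    got <- records |>
      dplyr::mutate(dplyr::across(dplyr::all_of(by), as.character)) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(
        n = sum(!is.na(.data[[response]])),
        mean = mean(.data[[response]], na.rm = TRUE),
        sem = stats::sd(.data[[response]], na.rm = TRUE) /
          sqrt(sum(!is.na(.data[[response]]))),
        .groups = "drop"
      )
    out <- dplyr::left_join(grid, got, by = by)
    out$n[is.na(out$n)] <- 0L
    out$mean[out$n == 0] <- NA_real_
    out$sem[out$n < 2] <- NA_real_
    out$term <- paste(by, collapse = " x ")
    out
  }
  blocks <- c(purrr::map(factors, ~ summarise_by(.x)),
              if (length(factors) > 1) list(summarise_by(factors)))
  dplyr::bind_rows(blocks) |>
    dplyr::relocate("term") |>
    dplyr::relocate("n", "mean", "sem", .after = dplyr::last_col())
}

#' Pearson correlation between the two log10 populations
#'
#' Pearson r on paired log10 abundances (methanogen vs protozoa), with the
#' two-sided p-value from the t transform on n - 2 degrees of freedom.
#' Invariant to positive affine transforms of either variable.
#'
#' @param x Either a data frame holding the two columns, or the methanogen
#'   numeric vector.
#' @param y Protozoa numeric vector (when `x` is a vector), or ignored.
#' @param methanogen,protozoa Column names used when `x` is a data frame.
#' @return A one-row tibble (`r`, `p_value`, `n`, `conf_low`, `conf_high`).
#' @export
#' @examples
#' recs <- simulate_culture_dataset(cfg = sim_config(seed = 5), n_per_cell = 5)
#' population_correlation(recs)
population_correlation <- function(x, y = NULL,
                                   methanogen = "methanogen_log10",
                                   protozoa = "protozoa_log10") {
  if (is.data.frame(x)) {
    stopifnot(all(c(methanogen, protozoa) %in% names(x)))
    m <- x[[methanogen]]
    p <- x[[protozoa]]
  } else {
    m <- x
    p <- y
  }
  ok <- stats::complete.cases(m, p)
  m <- m[ok]
  p <- p[ok]
  if (length(m) < 3) {
    rlang::abort("Need >= 3 complete pairs.",
                 class = "cpcrquant_error_insufficient_points")
  }
  if (stats::sd(m) == 0 || stats::sd(p) == 0) {
    rlang::abort("Correlation undefined: a series has zero variance.",
                 class = "cpcrquant_error_undefined_correlation")
  }
  ct <- stats::cor.test(m, p, method = "pearson")
  ci <- if (is.null(ct$conf.int)) c(NA_real_, NA_real_) else ct$conf.int
  tibble::tibble(
    r = unname(ct$estimate), p_value = ct$p.value, n = length(m),
    conf_low = ci[1], conf_high = ci[2]
  )
}
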