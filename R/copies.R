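#' DNA copy number from mass, and back
#'
#' Converts a mass of double-stranded DNA to molecule copies via
#' `copies = amount_ng * N_A / (length_bp * 1e9 * 650)`, where `N_A` is
#' Avogadro's number (6.022e23 / mol), 650 g/mol/bp is the mean molar mass
#' of a double-stranded base pair, and 1e9 converts ng to g. The conversion
#' is exactly linear in mass and inversely proportional to fragment length;
#' `mass_from_copies()` is its exact inverse.
#'
#' @param amount_ng Mass of dsDNA in nanograms (>= 0); vectorized.
#' @param copies Molecule count (>= 0); vectorized.
#' @param length_bp Fragment length in base pairs (> 0).
#' @return `copies_from_mass()`: copies; `mass_from_copies()`: nanograms.
#' @export
#' @examples
#' copies_from_mass(1, 296)                 # ~3.13e9 copies per ng
#' mass_from_copies(copies_from_mass(5, 196), 196)  # 5 ng back
copies_from_mass <- function(amount_ng, length_bp) {
  check_mass_args(amount_ng, length_bp)
  amount_ng * .const$avogadro / (length_bp * .const$ng_per_g * .const$bp_g_mol)
}

#' @rdname copies_from_mass
#' @export
mass_from_copies <- function(copies, length_bp) {
  check_mass_args(copies, length_bp)
  copies * length_bp * .const$ng_per_g * .const$bp_g_mol / .const$avogadro
}

#' Physical constants used by the copy-number conversion
#'
#' @return A tibble with one row per constant (`avogadro`, `bp_g_mol`,
#'   `ng_per_g`) and columns `constant`, `value`, `unit`.
#' @export
physical_constants <- function() {
  tibble::tibble(
    constant = c("avogadro", "bp_g_mol", "ng_per_g"),
    value = c(.const$avogadro, .const$bp_g_mol, .const$ng_per_g),
    unit = c("molecules/mol", "g/mol per bp (dsDNA)", "ng/g")
  )
}

.const <- list(avogadro = 6.022e23, bp_g_mol = 650, ng_per_g = 1e9)

check_mass_args <- function(amount, length_bp) {
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    rlang::abort("`length_bp` must be positive and finite.",
                 class = "cpcrquant_error_bad_input")
  }
  if (any(!is.finite(amount)) || any(amount < 0)) {
    rlang::abort("Masses/copy numbers must be finite and >= 0.",
                 class = "cpcrquant_error_bad_input")
  }
  invisible(TRUE)
}
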