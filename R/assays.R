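#' Amplicon specification
#'
#' Describes one PCR fragment taking part in a competitive amplification:
#' either the genomic target or the size-modified competitor (internal
#' standard) that shares its primer sites.
#'
#' @param name Fragment label, e.g. `"target"` or `"competitor"`.
#' @param length_bp Amplicon length in base pairs (> 0).
#' @param role One of `"target"`, `"competitor"`.
#' @return A one-row tibble with columns `name`, `length_bp`, `role`.
#' @export
#' @examples
#' amplicon_spec("target", 296, "target")
amplicon_spec <- function(name, length_bp, role = c("target", "competitor")) {
  role <- rlang::arg_match(role)
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(length_bp) || length(length_bp) != 1 || length_bp <= 0) {
    rlang::abort("`length_bp` must be a single positive number.",
                 class = "cpcrquant_error_bad_input")
  }
  tibble::tibble(name = name, length_bp = as.numeric(length_bp), role = role)
}

#' Competitive-PCR assay definitions
#'
#' An assay pairs a target amplicon with its shorter competitor and records
#' the cycle count used for co-amplification. The two built-in assays are
#' the rumen methanogen assay (16S rRNA, 296 bp target vs 196 bp
#' competitor, 34 cycles) and the rumen protozoa assay (18S rRNA, 360 bp
#' target vs 235 bp competitor, 30 cycles).
#'
#' @param taxon Assay label.
#' @param target_length_bp,competitor_length_bp Fragment lengths in bp; the
#'   target must be the longer fragment (it migrates less far on the gel,
#'   which is how bands are assigned downstream).
#' @param cycles Number of PCR cycles.
#' @return A list of class `cpcr_assay` with elements `taxon`, `target`,
#'   `competitor` (amplicon tibbles) and `cycles`.
#' @export
#' @examples
#' methanogen_assay()
#' protozoa_assay()$competitor
assay_spec <- function(taxon, target_length_bp, competitor_length_bp, cycles) {
  if (target_length_bp <= competitor_length_bp) {
    rlang::abort(
      "The target amplicon must be longer than its competitor (band assignment is by migration order).",
      class = "cpcrquant_error_bad_input"
    )
  }
  structure(
    list(
      taxon = taxon,
      target = amplicon_spec("target", target_length_bp, "target"),
      competitor = amplicon_spec("competitor", competitor_length_bp, "competitor"),
      cycles = as.integer(cycles)
    ),
    class = "cpcr_assay"
  )
}

#' @rdname assay_spec
#' @export
methanogen_assay <- function() assay_spec("methanogen", 296, 196, cycles = 34)

#' @rdname assay_spec
#' @export
protozoa_assay <- function() assay_spec("protozoa", 360, 235, cycles = 30)

#' @export
print.cpcr_assay <- function(x, ...) {
  cat(sprintf("<cpcr_assay> %s: target %g bp vs competitor %g bp, %d cycles\n",
              x$taxon, x$target$length_bp, x$competitor$length_bp, x$cycles))
  invisible(x)
}
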