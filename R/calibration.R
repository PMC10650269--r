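#' Fit a competitive-PCR calibration line and its equivalence point
#'
#' Ordinary least squares of `y = log10(target_intensity /
#' competitor_intensity)` on `x = log10(competitor_copies)`. The
#' equivalence point is where the fitted line crosses `y = 0` — target and
#' competitor bands equally intense — so `equivalence_copies =
#' 10^(-intercept/slope)` estimates the target template copies per
#' reaction. A valid titration has a clearly negative slope (more
#' competitor suppresses the target band).
#'
#' Two intensity conventions are supported. `mode = "raw"` ratios the band
#' intensities as a densitometry tool reports them; since ethidium signal
#' scales with dsDNA mass, the raw ratio over-weights the longer target by
#' the length ratio, biasing the equivalence point upward by
#' `L_target / L_competitor` (0.18 log10 for 296/196). `mode = "molar"`
#' divides each intensity by its fragment length first, making the ratio
#' molar and the equivalence point unbiased; it is the recommended mode and
#' requires `assay`.
#'
#' @param points A data frame with columns `competitor_copies` (> 0),
#'   `target_intensity`, `competitor_intensity` (>= 0) and optionally
#'   `usable` (logical). Points with either intensity zero (log-ratio
#'   undefined) or `usable = FALSE` are dropped, not imputed; at least 3
#'   must remain.
#' @param mode `"raw"` (default) or `"molar"`.
#' @param assay The [assay_spec()] providing fragment lengths (required for
#'   `mode = "molar"`).
#' @return An object of class `cpcr_calibration`: list with `slope`,
#'   `intercept`, `r_squared`, `n_points`, `equivalence_copies`, `mode`,
#'   `extrapolated` (equivalence outside the dilution range), `data` (the
#'   points used, with `log10_copies` and `log10_ratio`), and the
#'   underlying `lm` fit in `model`. Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   competitor_copies = 10^(4:6),
#'   target_intensity = 10^(1:-1),
#'   competitor_intensity = 1
#' )
#' glance(build_calibration(pts))
build_calibration <- function(points, mode = c("raw", "molar"),
                              assay = NULL) {
  mode <- rlang::arg_match(mode)
  points <- tibble::as_tibble(points)
  need <- c("competitor_copies", "target_intensity", "competitor_intensity")
  stopifnot(all(need %in% names(points)))
  if (!"usable" %in% names(points)) points$usable <- TRUE
  points$usable <- points$usable &
    points$target_intensity > 0 & points$competitor_intensity > 0 &
    points$competitor_copies > 0
  used <- dplyr::filter(points, .data$usable)
  if (nrow(used) < 3) {
    rlang::abort(sprintf(
      "Calibration needs >= 3 usable dilution points (got %d).", nrow(used)),
      class = "cpcrquant_error_insufficient_points")
  }

  ti <- used$target_intensity
  ci <- used$competitor_intensity
  if (mode == "molar") {
    if (is.null(assay)) {
      rlang::abort("`mode = \"molar\"` needs `assay` for the fragment lengths.",
                   class = "cpcrquant_error_bad_input")
    }
    ti <- ti / assay$target$length_bp
    ci <- ci / assay$competitor$length_bp
  }
  used <- dplyr::mutate(used,
                        log10_copies = log10(.data$competitor_copies),
                        log10_ratio = log10(ti / ci))

  fit <- stats::lm(log10_ratio ~ log10_copies, data = used)
  # summary.lm warns on numerically perfect (noiseless) fits; harmless here
  fit_summary <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope >= 0 || abs(slope) < 0.1) {
    rlang::abort(sprintf(
      "No competition signal: calibration slope %.3g is not clearly negative.",
      slope), class = "cpcrquant_error_invalid_titration")
  }
  equivalence <- 10^(-intercept / slope)
  rng <- range(used$competitor_copies)
  structure(
    list(
      slope = slope,
      intercept = intercept,
      r_squared = fit_summary$r.squared,
      n_points = nrow(used),
      equivalence_copies = equivalence,
      mode = mode,
      extrapolated = equivalence < rng[1] || equivalence > rng[2],
      data = used,
      model = fit,
      assay = assay
    ),
    class = "cpcr_calibration"
  )
}

#' @export
print.cpcr_calibration <- function(x, ...) {
  cat(sprintf(
    "<cpcr_calibration> %s mode, %d points\n  slope %.4f, intercept %.4f, R^2 %.4f\n  equivalence %.4g copies/reaction (log10 %.3f)%s\n",
    x$mode, x$n_points, x$slope, x$intercept, x$r_squared,
    x$equivalence_copies, log10(x$equivalence_copies),
    if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' Tidy a cPCR calibration fit
#'
#' @param x A `cpcr_calibration`.
#' @param ... Unused.
#' @return `tidy()`: one row per regression term (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`); `glance()`: a one-row tibble with
#'   `slope`, `intercept`, `r_squared`, `n_points`, `equivalence_copies`,
#'   `log10_equivalence`, `mode`, `extrapolated`.
#' @export
tidy.cpcr_calibration <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.cpcr_calibration
#' @export
glance.cpcr_calibration <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    n_points = x$n_points, equivalence_copies = x$equivalence_copies,
    log10_equivalence = log10(x$equivalence_copies),
    mode = x$mode, extrapolated = x$extrapolated
  )
}

#' Plot a calibration line with its equivalence point
#'
#' @param object A `cpcr_calibration`.
#' @param ... Unused.
#' @return A ggplot: log10 intensity ratio vs log10 competitor copies, the
#'   fitted line, and the equivalence point where it crosses zero.
#' @export
autoplot.cpcr_calibration <- function(object, ...) {
  d <- object$data
  xeq <- log10(object$equivalence_copies)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_copies,
                                  y = .data$log10_ratio)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::annotate("point", x = xeq, y = 0, shape = 4, size = 3,
                      colour = "firebrick") +
    ggplot2::labs(
      x = "log10 competitor copies / reaction",
      y = "log10 (target / competitor) band intensity",
      title = sprintf("Equivalence point: %.3g copies/reaction (%s mode)",
                      object$equivalence_copies, object$mode)
    )
}
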