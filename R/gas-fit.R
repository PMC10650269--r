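#' Blank-correct a cumulative gas curve
#'
#' Subtracts, at every reading time, the mean volume of the blank syringes
#' (buffered rumen fluid only) from a substrate syringe's cumulative
#' volume. Blank means recorded on a different time grid are linearly
#' interpolated; outside the blank grid the nearest blank mean is carried
#' (flagged in the output). Slightly negative early-time corrected volumes
#' are retained — truncating them would bias the rate estimate.
#'
#' @param readings Tibble for one syringe: `time_h` (strictly increasing,
#'   > 0) and `volume_ml`; a `syringe_id` column is carried through.
#' @param blanks Tibble of blank readings (`time_h`, `volume_ml`, any
#'   number of syringes) or `NULL`.
#' @param on_missing_blank `"error"` (default) aborts when `blanks` is
#'   `NULL`; `"passthrough"` returns the readings uncorrected with
#'   `blank_corrected = FALSE`.
#' @param substrate_mg Nominal substrate dry matter, mg (metadata only).
#' @return A tibble (`syringe_id`, `time_h`, `volume_ml`,
#'   `blank_corrected`) with attribute `substrate_mg`.
#' @export
#' @examples
#' subs <- tibble::tibble(time_h = c(2, 4, 8), volume_ml = c(10, 18, 30))
#' blk <- tibble::tibble(time_h = c(2, 4, 8), volume_ml = c(1, 2, 3))
#' assemble_curve(subs, blk)
assemble_curve <- function(readings, blanks = NULL,
                           on_missing_blank = c("error", "passthrough"),
                           substrate_mg = 500) {
  on_missing_blank <- rlang::arg_match(on_missing_blank)
  readings <- tibble::as_tibble(readings)
  stopifnot(all(c("time_h", "volume_ml") %in% names(readings)))
  if (any(diff(readings$time_h) <= 0) || any(readings$time_h <= 0)) {
    rlang::abort("`time_h` must be strictly increasing and > 0.",
                 class = "cpcrquant_error_bad_input")
  }
  sid <- if ("syringe_id" %in% names(readings)) readings$syringe_id[1] else NA_character_

  if (is.null(blanks) || nrow(blanks) == 0) {
    if (on_missing_blank == "error") {
      rlang::abort("No blank readings supplied for blank correction.",
                   class = "cpcrquant_error_missing_blanks")
    }
    out <- tibble::tibble(syringe_id = sid, time_h = readings$time_h,
                          volume_ml = readings$volume_ml,
                          blank_corrected = FALSE)
    attr(out, "substrate_mg") <- substrate_mg
    return(out)
  }

  blank_mean <- blanks |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(volume_ml = mean(.data$volume_ml), .groups = "drop") |>
    dplyr::arrange(.data$time_h)
  bm <- if (nrow(blank_mean) == 1) {
    rep(blank_mean$volume_ml, nrow(readings))
  } else {
    stats::approx(blank_mean$time_h, blank_mean$volume_ml,
                  xout = readings$time_h, rule = 2)$y
  }
  out <- tibble::tibble(syringe_id = sid, time_h = readings$time_h,
                        volume_ml = readings$volume_ml - bm,
                        blank_corrected = TRUE)
  attr(out, "substrate_mg") <- substrate_mg
  out
}

#' Fit the exponential gas model without lag
#'
#' Nonlinear least squares of `y = V (1 - exp(-k t))` on a cumulative gas
#' curve (Levenberg-Marquardt). The model has no lag term and passes
#' through the origin implicitly; t = 0 is not an observation. Starting
#' values: `V0 = 1.05 * max(y)`, and `k0` from the slope of
#' `ln(1 - y/V0)` vs `t` over points with `y < 0.9 V0`; bounds
#' `V in (0, 10 max(y)]`, `k in (0, 2]`. Convergence uses a relative RSS
#' tolerance of 1e-10 and a parameter-step tolerance of 1e-8. If the solver
#' fails (e.g. noise-dominated, non-increasing data) the fit is returned
#' with `converged = FALSE` and the last/initial iterate plus a diagnostic.
#'
#' @param curve A tibble with `time_h` and `volume_ml` (one syringe),
#'   e.g. from [assemble_curve()] or [simulate_gas_curve()]. Needs >= 4
#'   observations spanning at least one doubling of time.
#' @return A `gas_kinetics_fit` (see [gas_kinetics_fit()]) with `V`, `k`,
#'   `T0_5`, `G0_5`, `rss`, `converged`, `n_obs`, the data, and the
#'   underlying `nls` object in `model` (when available).
#' @export
#' @examples
#' curve <- simulate_gas_curve(100, 0.1, sim_config(seed = 1, gas_noise_sd = 0))
#' fit_exponential(curve)
fit_exponential <- function(curve) {
  curve <- tibble::as_tibble(curve)
  stopifnot(all(c("time_h", "volume_ml") %in% names(curve)))
  t <- curve$time_h
  y <- curve$volume_ml
  if (length(t) < 4) {
    rlang::abort("Need >= 4 observations to fit the gas model.",
                 class = "cpcrquant_error_insufficient_points")
  }
  if (any(diff(t) <= 0) || any(t <= 0)) {
    rlang::abort("`time_h` must be strictly increasing and > 0.",
                 class = "cpcrquant_error_bad_input")
  }
  if (max(t) < 2 * min(t)) {
    rlang::abort("Observations must span at least one doubling of time.",
                 class = "cpcrquant_error_bad_input")
  }
  ymax <- max(y)
  if (ymax <= 0) {
    rlang::abort("All volumes are <= 0; nothing to fit.",
                 class = "cpcrquant_error_bad_input")
  }

  V0 <- 1.05 * ymax
  early <- y > 0 & y < 0.9 * V0
  k0 <- if (sum(early) >= 2) {
    sl <- stats::coef(stats::lm(log(1 - y[early] / V0) ~ t[early]))[2]
    max(min(-unname(sl), 2), 1e-3)
  } else 0.05

  sid <- if ("syringe_id" %in% names(curve)) curve$syringe_id[1] else NA_character_
  fit <- tryCatch(
    minpack.lm::nlsLM(
      volume_ml ~ V * (1 - exp(-k * time_h)),
      data = curve,
      start = list(V = V0, k = k0),
      lower = c(V = 1e-8, k = 1e-8),
      upper = c(V = 10 * ymax, k = 2),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-10, ptol = 1e-8, maxiter = 500)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(gas_kinetics_fit(V = V0, k = k0, rss = sum((y - gas_model(t, V0, k0))^2),
                            converged = FALSE, n_obs = length(t),
                            data = curve, syringe_id = sid,
                            diagnostic = conditionMessage(fit)))
  }
  co <- stats::coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  # fits dominated by noise: flag when the data carry no increasing trend
  if (stats::cor(t, y) <= 0) conv <- FALSE
  gas_kinetics_fit(V = unname(co["V"]), k = unname(co["k"]),
                   rss = sum(stats::resid(fit)^2), converged = conv,
                   n_obs = length(t), data = curve, model = fit,
                   syringe_id = sid)
}

#' Construct a gas-kinetics fit object
#'
#' Normally produced by [fit_exponential()]; constructing one directly from
#' known `V` and `k` (e.g. published estimates) gives access to the derived
#' statistics. By construction `T0_5 = ln(2)/k` and `G0_5 = V/2`.
#'
#' @param V Asymptotic gas volume, mL (> 0).
#' @param k Fractional rate, per hour (> 0).
#' @param rss Residual sum of squares, if known.
#' @param converged Solver convergence flag.
#' @param n_obs Number of observations fitted.
#' @param data,model,syringe_id,diagnostic Optional payloads.
#' @return A list of class `gas_kinetics_fit`.
#' @export
#' @examples
#' derived_stats(gas_kinetics_fit(V = 105.8, k = 0.0625))
gas_kinetics_fit <- function(V, k, rss = NA_real_, converged = NA,
                             n_obs = NA_integer_, data = NULL, model = NULL,
                             syringe_id = NA_character_, diagnostic = NULL) {
  if (isTRUE(converged) && (V <= 0 || k <= 0)) {
    rlang::abort("A converged fit requires V > 0 and k > 0.",
                 class = "cpcrquant_error_bad_input")
  }
  structure(
    list(V = V, k = k, T0_5 = log(2) / k, G0_5 = V / 2, rss = rss,
         converged = converged, n_obs = n_obs, data = data, model = model,
         syringe_id = syringe_id, diagnostic = diagnostic),
    class = "gas_kinetics_fit"
  )
}

#' Derived gas-kinetics statistics
#'
#' @param fit A `gas_kinetics_fit`.
#' @param times Optional time grid (h) at which to attach the predicted
#'   curve.
#' @return A one-row tibble (`V_ml`, `k_per_h`, `T0_5_h`, `G0_5_ml`) with,
#'   when `times` is given, a `predicted` list-column holding a tibble
#'   (`time_h`, `volume_ml`).
#' @export
derived_stats <- function(fit, times = NULL) {
  stopifnot(inherits(fit, "gas_kinetics_fit"))
  out <- tibble::tibble(V_ml = fit$V, k_per_h = fit$k,
                        T0_5_h = fit$T0_5, G0_5_ml = fit$G0_5)
  if (!is.null(times)) {
    out$predicted <- list(tibble::tibble(
      time_h = times, volume_ml = gas_model(times, fit$V, fit$k)))
  }
  out
}

#' @export
predict.gas_kinetics_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time_h
  gas_model(times, object$V, object$k)
}

#' @export
print.gas_kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "<gas_kinetics_fit> V = %.2f mL, k = %.4f /h, T0.5 = %.2f h, G0.5 = %.2f mL (rss %.3g, %s)\n",
    x$V, x$k, x$T0_5, x$G0_5, x$rss,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy a gas-kinetics fit
#'
#' @param x A `gas_kinetics_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with standard errors when the
#'   solver object is available; `glance()`: one-row fit summary including
#'   the derived half-time statistics.
#' @export
tidy.gas_kinetics_fit <- function(x, ...) {
  if (!is.null(x$model)) {
    s <- summary(x$model)$coefficients
    tibble::tibble(term = rownames(s), estimate = s[, "Estimate"],
                   std.error = s[, "Std. Error"],
                   statistic = s[, "t value"], p.value = s[, "Pr(>|t|)"])
  } else {
    tibble::tibble(term = c("V", "k"), estimate = c(x$V, x$k),
                   std.error = NA_real_, statistic = NA_real_,
                   p.value = NA_real_)
  }
}

#' @rdname tidy.gas_kinetics_fit
#' @export
glance.gas_kinetics_fit <- function(x, ...) {
  tibble::tibble(V = x$V, k = x$k, T0_5 = x$T0_5, G0_5 = x$G0_5,
                 rss = x$rss, converged = x$converged, n_obs = x$n_obs)
}

#' Plot a fitted gas curve
#'
#' @param object A `gas_kinetics_fit` holding its data.
#' @param ... Unused.
#' @return A ggplot of the observations and the fitted exponential curve,
#'   with the half-time point marked.
#' @export
autoplot.gas_kinetics_fit <- function(object, ...) {
  stopifnot(!is.null(object$data))
  d <- object$data
  grid <- tibble::tibble(
    time_h = seq(0, max(d$time_h), length.out = 200),
    volume_ml = gas_model(seq(0, max(d$time_h), length.out = 200),
                          object$V, object$k))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$volume_ml)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::annotate("point", x = object$T0_5, y = object$G0_5,
                      shape = 4, size = 3, colour = "firebrick") +
    ggplot2::labs(x = "Incubation time (h)", y = "Cumulative gas (mL)",
                  title = sprintf("V = %.1f mL, k = %.3f /h, T0.5 = %.1f h",
                                  object$V, object$k))
}

#' Methane fraction of total gas
#'
#' @param ch4_volume_ml CH4 volume, mL (0 <= CH4 <= total).
#' @param total_gas_ml Total gas volume, mL (> 0).
#' @return `100 * ch4 / total`, percent; vectorized.
#' @export
#' @examples
#' methane_fraction(9.94, 79.5)
methane_fraction <- function(ch4_volume_ml, total_gas_ml) {
  if (any(total_gas_ml <= 0)) {
    rlang::abort("`total_gas_ml` must be > 0.",
                 class = "cpcrquant_error_bad_input")
  }
  if (any(ch4_volume_ml < 0) || any(ch4_volume_ml > total_gas_ml)) {
    rlang::abort("CH4 volume must lie in [0, total gas].",
                 class = "cpcrquant_error_bad_input")
  }
  100 * ch4_volume_ml / total_gas_ml
}

#' Fit gas curves for every syringe in a long table
#'
#' Convenience wrapper: blank-corrects (using the table's flagged blank
#' syringes) and fits each substrate syringe, returning one row per
#' syringe.
#'
#' @param gas_data Long tibble (`syringe_id`, `is_blank`, `time_h`,
#'   `volume_ml`).
#' @param blank_correct Apply blank correction (requires blank rows).
#' @return A tibble (`syringe_id`, `V`, `k`, `T0_5`, `G0_5`, `rss`,
#'   `converged`, `n_obs`).
#' @export
fit_gas_curves <- function(gas_data, blank_correct = TRUE) {
  gas_data <- tibble::as_tibble(gas_data)
  stopifnot(all(c("syringe_id", "is_blank", "time_h", "volume_ml") %in%
                  names(gas_data)))
  blanks <- dplyr::filter(gas_data, .data$is_blank)
  subs <- dplyr::filter(gas_data, !.data$is_blank)
  subs |>
    dplyr::group_by(.data$syringe_id) |>
    dplyr::group_map(function(d, key) {
      d$syringe_id <- key$syringe_id
      curve <- if (blank_correct) {
        assemble_curve(d, blanks)
      } else {
        assemble_curve(d, NULL, on_missing_blank = "passthrough")
      }
      g <- glance(fit_exponential(curve))
      dplyr::bind_cols(tibble::tibble(syringe_id = key$syringe_id), g)
    }) |>
    purrr::list_rbind()
}
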