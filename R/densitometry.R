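#' Detect bands on a lane profile
#'
#' Finds local maxima and ranks them by topographic prominence (peak height
#' above the higher of the two saddles separating it from taller terrain or
#' the profile edge), keeping the `expected_bands` most prominent and
#' returning them in migration order. This is the profile-based equivalent
#' of picking bands in an image-analysis gel tool.
#'
#' @param profile A tibble with columns `position` (strictly increasing)
#'   and `intensity` (finite); at least 8 samples. A `lane_id` column, if
#'   present, is used in error messages.
#' @param expected_bands Number of bands that must be found (>= 1).
#' @param min_prominence Minimum prominence as a fraction of the profile's
#'   maximum intensity; candidates below it are discarded.
#' @return A tibble (`band_index`, `position`, `height`, `prominence`,
#'   `sample`) ordered by position.
#' @export
#' @examples
#' lane <- render_gel_lane(
#'   tibble::tibble(length_bp = c(296, 196), mass_ng = c(4, 4)),
#'   sim_config(seed = 2)
#' )
#' detect_bands(lane, expected_bands = 2)
detect_bands <- function(profile, expected_bands, min_prominence = 0.005) {
  check_profile(profile)
  if (expected_bands < 1) {
    rlang::abort("`expected_bands` must be >= 1.",
                 class = "cpcrquant_error_bad_input")
  }
  y <- profile$intensity
  pk <- peak_prominences(y)
  keep <- pk$prominence >= min_prominence * max(y)
  pk <- pk[keep, , drop = FALSE]
  if (nrow(pk) < expected_bands) {
    lane <- if ("lane_id" %in% names(profile)) profile$lane_id[1] else "<unnamed>"
    rlang::abort(
      sprintf("Lane %s: found %d band(s) where %d expected.",
              lane, nrow(pk), expected_bands),
      class = "cpcrquant_error_band_shortfall"
    )
  }
  pk <- pk[order(-pk$prominence)[seq_len(expected_bands)], , drop = FALSE]
  pk <- pk[order(pk$sample), , drop = FALSE]
  tibble::tibble(
    band_index = seq_len(nrow(pk)),
    position = profile$position[pk$sample],
    height = pk$height,
    prominence = pk$prominence,
    sample = pk$sample
  )
}

#' Rubber-band baseline under an integration window
#'
#' The baseline is the chord joining the profile values at the window's two
#' endpoints — the usual gel-densitometry background convention. Adding any
#' constant to the profile leaves the net (above-chord) signal unchanged.
#'
#' @param profile A lane profile tibble (`position`, `intensity`).
#' @param bounds Numeric length-2: the window's position limits (inside the
#'   profile's range).
#' @return The window rows with added columns `baseline` and `net`
#'   (`intensity - baseline`), plus attributes `raw_area`, `baseline_area`
#'   and `net_area` (trapezoidal integrals over the window).
#' @export
subtract_baseline <- function(profile, bounds) {
  check_profile(profile, min_samples = 2)
  bounds <- sort(as.numeric(bounds))
  rng <- range(profile$position)
  if (bounds[1] < rng[1] || bounds[2] > rng[2]) {
    rlang::abort("Integration window must lie inside the profile.",
                 class = "cpcrquant_error_bad_input")
  }
  idx <- which(profile$position >= bounds[1] & profile$position <= bounds[2])
  if (length(idx) < 2) {
    rlang::abort("Integration window covers fewer than 2 samples.",
                 class = "cpcrquant_error_bad_input")
  }
  win <- profile[idx, , drop = FALSE]
  x <- win$position
  y <- win$intensity
  chord <- y[1] + (y[length(y)] - y[1]) * (x - x[1]) / (x[length(x)] - x[1])
  out <- dplyr::mutate(win, baseline = chord, net = .data$intensity - chord)
  attr(out, "raw_area") <- pracma::trapz(x, y)
  attr(out, "baseline_area") <- pracma::trapz(x, chord)
  attr(out, "net_area") <- pracma::trapz(x, y - chord)
  out
}

#' Quantify the target and competitor bands of one lane
#'
#' Detects the two bands, assigns the earlier-migrating peak (smaller
#' position, longer fragment) to the target and the farther peak to the
#' competitor — assignment is by migration order, never by intensity —
#' estimates each peak's width from its half-prominence crossings, and
#' integrates each band over `centre +/- k_sigma * sigma` with a
#' rubber-band baseline. When the two windows collide they are truncated at
#' the inter-peak minimum and flagged.
#'
#' @param profile A lane profile tibble (`position`, `intensity`, optional
#'   `lane_id`).
#' @param assay The [assay_spec()] naming the two fragments.
#' @param k_sigma Half-width of the integration window in estimated peak
#'   sigmas.
#' @param min_prominence Passed to [detect_bands()].
#' @return A two-row tibble (`lane_id`, `band`, `length_bp`, `band_index`,
#'   `peak_position`, `lower`, `upper`, `raw_area`, `baseline_area`,
#'   `net_intensity`, `overlap`, `clamped`): rows `target`, `competitor`.
#'   Negative net areas are clamped to 0 with `clamped = TRUE`.
#' @export
quantify_lane <- function(profile, assay = methanogen_assay(),
                          k_sigma = 4, min_prominence = 0.005) {
  peaks <- detect_bands(profile, expected_bands = 2,
                        min_prominence = min_prominence)
  lane <- if ("lane_id" %in% names(profile)) profile$lane_id[1] else NA_character_
  x <- profile$position
  y <- profile$intensity

  sigma <- purrr::map_dbl(seq_len(2), function(i) {
    estimate_peak_sigma(x, y, peaks$sample[i], peaks$prominence[i],
                        peaks$height[i])
  })
  lower <- peaks$position - k_sigma * sigma
  upper <- peaks$position + k_sigma * sigma

  overlap <- upper[1] > lower[2]
  if (overlap) {
    # truncate both windows at the inter-peak minimum
    span <- peaks$sample[1]:peaks$sample[2]
    cut <- x[span[which.min(y[span])]]
    upper[1] <- min(upper[1], cut)
    lower[2] <- max(lower[2], cut)
  }
  rng <- range(x)
  lower <- pmax(lower, rng[1])
  upper <- pmin(upper, rng[2])

  rows <- purrr::map(seq_len(2), function(i) {
    win <- subtract_baseline(profile, c(lower[i], upper[i]))
    net <- attr(win, "net_area")
    tibble::tibble(
      band_index = i,
      peak_position = peaks$position[i],
      lower = lower[i], upper = upper[i],
      raw_area = attr(win, "raw_area"),
      baseline_area = attr(win, "baseline_area"),
      net_intensity = max(net, 0),
      overlap = overlap,
      clamped = net < 0
    )
  })
  out <- purrr::list_rbind(rows)
  # earlier peak = longer fragment = target
  out <- dplyr::bind_cols(
    tibble::tibble(
      lane_id = lane,
      band = c("target", "competitor"),
      length_bp = c(assay$target$length_bp, assay$competitor$length_bp)
    ),
    out
  )
  out
}

check_profile <- function(profile, min_samples = 8) {
  if (!all(c("position", "intensity") %in% names(profile))) {
    rlang::abort("A lane profile needs `position` and `intensity` columns.",
                 class = "cpcrquant_error_bad_input")
  }
  if (nrow(profile) < min_samples) {
    rlang::abort(sprintf("Profile has fewer than %d samples.", min_samples),
                 class = "cpcrquant_error_bad_input")
  }
  if (any(diff(profile$position) <= 0)) {
    rlang::abort("`position` must be strictly increasing.",
                 class = "cpcrquant_error_bad_input")
  }
  if (any(!is.finite(profile$intensity))) {
    rlang::abort("`intensity` must be finite.",
                 class = "cpcrquant_error_bad_input")
  }
  invisible(TRUE)
}

# Local maxima with topographic prominence. For each maximum, walk out on
# each side to the nearest strictly higher sample (or the edge); the
# reference level is the higher of the two interval minima, and prominence
# is height minus reference.
peak_prominences <- function(y) {
  n <- length(y)
  is_max <- which(diff(sign(diff(y))) < 0) + 1
  # plateaus: also accept points higher than both immediate neighbours
  if (length(is_max) == 0) {
    return(data.frame(sample = integer(), height = numeric(),
                      prominence = numeric()))
  }
  prom <- vapply(is_max, function(i) {
    h <- y[i]
    left <- if (i == 1) h else {
      seg <- y[1:(i - 1)]
      higher <- which(seg > h)
      lo <- if (length(higher)) max(higher) + 1 else 1
      min(y[lo:(i - 1)])
    }
    right <- if (i == n) h else {
      seg <- y[(i + 1):n]
      higher <- which(seg > h)
      hi <- if (length(higher)) i + min(higher) - 1 else n
      min(y[(i + 1):hi])
    }
    h - max(left, right)
  }, numeric(1))
  data.frame(sample = is_max, height = y[is_max], prominence = prom)
}

# Peak sd from the half-prominence crossings (FWHM / 2.3548), with linear
# interpolation between samples; falls back to one-sided width at an edge.
estimate_peak_sigma <- function(x, y, sample, prominence, height) {
  half <- height - prominence / 2
  n <- length(y)
  cross <- function(step) {
    j <- sample
    repeat {
      nxt <- j + step
      if (nxt < 1 || nxt > n) return(NA_real_)
      if (y[nxt] <= half) {
        frac <- (y[j] - half) / (y[j] - y[nxt])
        return(x[j] + frac * (x[nxt] - x[j]))
      }
      j <- nxt
    }
  }
  l <- cross(-1L)
  r <- cross(1L)
  if (is.na(l) && is.na(r)) return(diff(range(x)) / 20)
  if (is.na(l)) l <- 2 * x[sample] - r
  if (is.na(r)) r <- 2 * x[sample] - l
  (r - l) / (2 * sqrt(2 * log(2)))
}
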