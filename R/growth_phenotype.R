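#' Correct optical density readings for reader non-linearity
#'
#' Evaluates the cubic calibration polynomial
#' \deqn{x_{Adj} = -0.01454 + 1.231x - 0.6393x^2 + 0.4985x^3}
#' derived from an OD ladder spanning the reader's dynamic range
#' (0-2 OD_560). The polynomial is strictly increasing on that range (its
#' derivative has a negative discriminant), so the correction is invertible.
#' Apply once, after background correction; the function is not idempotent.
#'
#' @param x background-corrected OD_560 readings (vector ok). Values outside
#'   [0, 2] trigger a warning but are still evaluated.
#' @return adjusted OD_560 values, elementwise.
#' @export
adjust_od <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("OD input must be finite numeric")
  }
  if (any(x < 0 | x > 2)) {
    warning("OD values outside the calibrated range [0, 2]")
  }
  -0.01454 + 1.231 * x - 0.6393 * x^2 + 0.4985 * x^3
}

# numeric inverse of the calibration cubic on its monotone range (used by the
# growth-curve simulator to emulate the raw instrument response)
inverse_adjust_od <- function(y) {
  vapply(y, function(yi) {
    stats::uniroot(function(x) adjust_od_quiet(x) - yi,
                   lower = -0.5, upper = 3, tol = 1e-12)$root
  }, numeric(1))
}

adjust_od_quiet <- function(x) -0.01454 + 1.231 * x - 0.6393 * x^2 + 0.4985 * x^3

#' Background-correct OD readings against blank wells
#'
#' Subtracts the per-timepoint mean of the blank wells and floors at zero.
#'
#' @param od numeric vector (one well) or matrix (timepoints x wells).
#' @param blanks numeric vector (one blank well or per-timepoint means) or
#'   matrix (timepoints x blank wells); at least one blank well is required.
#' @return corrected readings, same shape as `od`.
#' @export
background_correct <- function(od, blanks) {
  if (missing(blanks) || is.null(blanks) || length(blanks) == 0) {
    stop("at least one blank well is required")
  }
  blank_mean <- if (is.matrix(blanks)) rowMeans(blanks) else as.numeric(blanks)
  n_t <- if (is.matrix(od)) nrow(od) else length(od)
  if (length(blank_mean) == 1) blank_mean <- rep(blank_mean, n_t)
  if (length(blank_mean) != n_t) {
    stop("blank series length does not match the OD series")
  }
  pmax(od - blank_mean, 0)
}

#' Segment a growth curve into pre- and post-shift phases
#'
#' Computes a growth-rate series as the rolling-window least-squares slope of
#' ln(OD) versus time, then looks for a diauxic shift: the deepest local
#' minimum of the rate series lying between two local maxima that each exceed
#' a floor (`rate_floor_frac` of the global maximum rate). If no minimum
#' qualifies, no shift is reported and the post-shift fields are absent
#' (`NA`). Windows containing non-positive OD values are skipped.
#'
#' @param curve a `growth_curve`; the adjusted OD is used when present,
#'   otherwise the raw OD.
#' @param smoothing_window window width in readings (default 5).
#' @param rate_floor_frac fraction of the global maximum rate a local maximum
#'   must exceed to qualify (default 0.1).
#' @param dip_frac a candidate minimum only qualifies as a shift when its
#'   rate falls below this fraction of the smaller flanking maximum (0.5);
#'   suppresses spurious shifts on effectively single-exponential curves.
#' @param min_od windows containing readings below this OD are skipped
#'   (0.05): near the blank level the log-slope is dominated by reader noise.
#' @return a `phase_annotation` list: `shift_time` (h, `NA` if none),
#'   `pre_rate`, `post_rate` (1/h; `post_rate` `NA` without a shift),
#'   `pre_window`, `post_window` (time intervals used).
#' @export
detect_phases <- function(curve, smoothing_window = 5, rate_floor_frac = 0.1,
                          dip_frac = 0.5, min_od = 0.05) {
  od <- curve$od_adjusted %||% curve$od_raw
  time <- curve$time
  n <- length(time)
  if (n < 10) stop("at least 10 timepoints are required")
  w <- as.integer(smoothing_window)
  if (w < 3) stop("smoothing_window must be >= 3 readings")
  n_win <- n - w + 1
  centers <- rates <- rep(NA_real_, n_win)
  for (i in seq_len(n_win)) {
    idx <- i:(i + w - 1)
    y <- od[idx]
    if (any(y < min_od) || any(y <= 0)) next  # window skipped
    t <- time[idx]
    ly <- log(y)
    rates[i] <- stats::cov(t, ly) / stats::var(t)
    centers[i] <- mean(t)
  }
  keep <- !is.na(rates)
  if (!any(keep)) stop("all windows contained non-positive OD values")
  rates <- rates[keep]
  centers <- centers[keep]
  # light running-mean smoothing stabilises the extrema analysis under noise
  if (length(rates) >= 3) {
    rates <- stats::filter(rates, rep(1 / 3, 3))
    rates[1] <- rates[2]; rates[length(rates)] <- rates[length(rates) - 1]
    rates <- as.numeric(rates)
  }
  m <- length(rates)
  if (m < 3) {
    return(phase_annotation(NA, max(rates, 0), NA, range(centers), NULL))
  }
  g_max <- max(rates)
  floor_rate <- rate_floor_frac * g_max
  is_max <- is_min <- rep(FALSE, m)
  for (i in 2:(m - 1)) {
    is_max[i] <- rates[i] >= rates[i - 1] && rates[i] >= rates[i + 1] &&
      (rates[i] > rates[i - 1] || rates[i] > rates[i + 1])
    is_min[i] <- rates[i] <= rates[i - 1] && rates[i] <= rates[i + 1] &&
      (rates[i] < rates[i - 1] || rates[i] < rates[i + 1])
  }
  # endpoints can host the flanking maxima
  is_max[1] <- rates[1] > rates[2]
  is_max[m] <- rates[m] > rates[m - 1]
  qual_max <- which(is_max & rates > floor_rate)
  cand <- which(is_min)
  # a genuine shift dips well below both flanking growth maxima
  cand <- cand[vapply(cand, function(i) {
    before <- qual_max[qual_max < i]
    after <- qual_max[qual_max > i]
    length(before) > 0 && length(after) > 0 &&
      rates[i] < dip_frac * min(max(rates[before]), max(rates[after]))
  }, logical(1))]
  if (!length(cand)) {
    pre_rate <- max(rates, 0)
    return(phase_annotation(NA, pre_rate, NA, range(centers), NULL))
  }
  shift_i <- cand[which.min(rates[cand])]
  shift_time <- centers[shift_i]
  pre_rate <- max(rates[centers <= shift_time], 0)
  post_rate <- max(rates[centers > shift_time], 0)
  phase_annotation(shift_time, pre_rate, post_rate,
                   c(min(centers), shift_time), c(shift_time, max(centers)))
}

phase_annotation <- function(shift_time, pre_rate, post_rate,
                             pre_window, post_window) {
  structure(list(shift_time = shift_time,
                 pre_rate = max(pre_rate, 0),
                 post_rate = if (is.na(post_rate)) NA_real_ else max(post_rate, 0),
                 pre_window = pre_window,
                 post_window = post_window),
            class = "phase_annotation")
}

#' @export
print.phase_annotation <- function(x, ...) {
  if (is.na(x$shift_time)) {
    cat(sprintf("phase_annotation: no shift detected; rate %.3f 1/h\n", x$pre_rate))
  } else {
    cat(sprintf("phase_annotation: shift at %.2f h; pre %.3f, post %.3f 1/h\n",
                x$shift_time, x$pre_rate, x$post_rate))
  }
  invisible(x)
}

#' Background-correct and calibrate a growth curve
#'
#' Convenience wrapper applying [background_correct()] then [adjust_od()],
#' in the order the readings are processed upstream of rate estimation.
#'
#' @param curve a `growth_curve`.
#' @param blanks blank-well readings (see [background_correct()]); `NULL`
#'   skips background correction.
#' @return the curve with `od_adjusted` filled in.
#' @export
adjust_curve <- function(curve, blanks = NULL) {
  od <- curve$od_raw
  if (!is.null(blanks)) od <- background_correct(od, blanks)
  curve$od_adjusted <- suppressWarnings(adjust_od(od))
  curve
}
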