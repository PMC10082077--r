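#' Simulate a diauxic growth curve
#'
#' Noiseless expectation is piecewise exponential in OD: exponential growth
#' at `pre_rate` until `shift_time`, a lag plateau of length `lag`, then
#' exponential growth at `post_rate`. Gaussian reading noise is added and the
#' readings are clipped to the plate-reader range [0, 2] OD. With
#' `instrument_response = TRUE` the true OD is passed through the inverse of
#' the cubic correction polynomial (see [adjust_od()]), emulating a reader
#' whose raw signal needs that correction.
#'
#' @param pre_rate,post_rate specific growth rates (1/h); must be positive.
#' @param shift_time time of the diauxic shift (h).
#' @param lag plateau length at the shift (h).
#' @param noise_sd standard deviation of additive reading noise (OD units).
#' @param dt sampling interval (h); the study protocol reads every 20 min.
#' @param horizon total duration (h).
#' @param od0 initial OD.
#' @param well_id,strain identifiers carried in the result.
#' @param instrument_response apply the inverse correction polynomial.
#' @param seed integer seed (`NULL` = use current RNG state).
#' @return a `growth_curve`: list with `time`, `od_raw`, `od_adjusted`
#'   (NULL until adjusted), `well_id`, `strain`.
#' @export
simulate_growth_curve <- function(pre_rate, post_rate, shift_time, lag = 2,
                                  noise_sd = 0, dt = 1 / 3, horizon = 48,
                                  od0 = 0.01, well_id = "A1", strain = "WT",
                                  instrument_response = FALSE, seed = NULL) {
  stopifnot_scalar_number(pre_rate, "pre_rate", positive = TRUE)
  stopifnot_scalar_number(post_rate, "post_rate", positive = TRUE)
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  stopifnot_scalar_number(horizon, "horizon", positive = TRUE)
  if (lag < 0) stop("lag must be >= 0")
  time <- seq(0, horizon, by = dt)
  od <- ifelse(time < shift_time,
               od0 * exp(pre_rate * time),
        ifelse(time < shift_time + lag,
               od0 * exp(pre_rate * shift_time),
               od0 * exp(pre_rate * shift_time) *
                 exp(post_rate * (time - shift_time - lag))))
  if (instrument_response) od <- inverse_adjust_od(pmin(od, 2))
  od <- with_seed(seed, od + if (noise_sd > 0) stats::rnorm(length(od), 0, noise_sd) else 0)
  od <- pmin(pmax(od, 0), 2)
  structure(list(time = time, od_raw = od, od_adjusted = NULL,
                 well_id = well_id, strain = strain),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("growth_curve %s (%s): %d readings over %.1f h, OD %.3f-%.3f\n",
              x$well_id, x$strain, length(x$time), max(x$time),
              min(x$od_raw), max(x$od_raw)))
  invisible(x)
}
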