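#' Kinetic parameters for the reporter translocation model
#'
#' Parameterises the first-order relaxation model used by the synthetic
#' generator for kinase-translocation-reporter (KTR) dynamics. A KTR shifts
#' between nucleus and cytoplasm as the kinase phosphorylates it, so the
#' cytoplasm/nucleus (C/N) intensity ratio tracks kinase activity. The
#' generator's model is a deliberate stand-in (the simplest dynamics that
#' reproduce the observed nucleus-to-cytoplasm translocation over a ~120 min
#' movie sampled every 10 min), not a biophysical calibration:
#' \deqn{dr/dt = (r_\infty(a) - r)/\tau, \quad
#'       r_\infty(a) = r_{min} + (r_{max} - r_{min})\,a}
#' with latent activity \eqn{a \in [0, 1]}.
#'
#' @param r_min baseline C/N ratio with the kinase fully inactive
#'   (nuclear-enriched reporter, e.g. under MEK or AKT inhibition).
#' @param r_max saturated C/N ratio with the kinase fully active
#'   (cytoplasm-enriched reporter, e.g. after FGF7 stimulation).
#' @param tau relaxation time constant, minutes.
#' @param noise_sd multiplicative intensity-noise scale used at render time
#'   (dimensionless standard deviation; 0 disables noise).
#' @return an object of class `kinetics_params`.
#' @export
kinetics_params <- function(r_min = 0.6, r_max = 1.8, tau = 20, noise_sd = 0.05) {
  if (!(is.numeric(r_min) && is.numeric(r_max) && r_min > 0 && r_min < r_max))
    stop("require 0 < r_min < r_max")
  if (!(is.numeric(tau) && tau > 0)) stop("tau must be > 0")
  if (!(is.numeric(noise_sd) && noise_sd >= 0)) stop("noise_sd must be >= 0")
  structure(list(r_min = r_min, r_max = r_max, tau = tau, noise_sd = noise_sd),
            class = "kinetics_params")
}

#' Latent kinase-activity trace
#'
#' A time series of latent kinase activity in `[0, 1]`, the driving input of
#' [simulate_ktr_kinetics()]. Activity 0 emulates full inhibition, 1 emulates
#' saturating stimulation; a step from 0 to 1 at the first frame emulates
#' ligand addition at the start of imaging.
#'
#' @param times sample times in minutes, strictly increasing, starting at 0.
#' @param activity latent activity values in `[0, 1]`, one per time.
#' @return an object of class `activity_trace`.
#' @export
activity_trace <- function(times, activity) {
  if (length(times) != length(activity))
    stop("times and activity must have equal length")
  if (length(times) < 1L || times[1] != 0)
    stop("times must start at 0")
  d <- diff(times)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1]
    stop(sprintf("times must be strictly increasing; offending index %d (t[%d]=%g, t[%d]=%g)",
                 i + 1L, i, times[i], i + 1L, times[i + 1]))
  }
  if (any(activity < 0 | activity > 1))
    stop("activity must lie in [0, 1]")
  structure(list(times = as.numeric(times), activity = as.numeric(activity)),
            class = "activity_trace")
}

#' Step activity trace (inhibited baseline, stimulation at a set time)
#'
#' @param times sample times in minutes.
#' @param t_on time at which activity steps from `low` to `high`.
#' @param low,high activity levels before/after the step.
#' @return an `activity_trace`.
#' @export
step_activity <- function(times, t_on = 0, low = 0, high = 1) {
  activity_trace(times, ifelse(times >= t_on, high, low))
}

#' Simulate the true C/N ratio of a KTR under a latent activity trace
#'
#' Integrates the first-order relaxation model with the activity held
#' constant over each sampling interval (zero-order hold), using the exact
#' exponential update per interval
#' \eqn{r_{k+1} = r_\infty(a_k) + (r_k - r_\infty(a_k)) e^{-\Delta t/\tau}},
#' so the result matches the closed-form solution for piecewise-constant
#' activity to machine precision. Output is deterministic and bounded in
#' `[r_min, r_max]` whenever `r0` is.
#'
#' @param activity an [activity_trace()].
#' @param params a [kinetics_params()].
#' @param r0 initial C/N ratio, within `[r_min, r_max]`.
#' @return numeric vector of true C/N ratios, one per time point.
#' @export
simulate_ktr_kinetics <- function(activity, params, r0 = params$r_min) {
  stopifnot(inherits(activity, "activity_trace"), inherits(params, "kinetics_params"))
  if (r0 < params$r_min || r0 > params$r_max)
    stop("r0 must lie in [r_min, r_max]")
  tt <- activity$times
  a <- activity$activity
  r <- numeric(length(tt))
  r[1] <- r0
  rinf <- params$r_min + (params$r_max - params$r_min) * a
  if (length(tt) > 1) {
    for (k in seq_len(length(tt) - 1L)) {
      dt <- tt[k + 1L] - tt[k]
      r[k + 1L] <- rinf[k] + (r[k] - rinf[k]) * exp(-dt / params$tau)
    }
  }
  r
}
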