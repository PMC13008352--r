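# Synthetic data generators emulating the statistical structure of the
# bead-tracking experiments, so every estimator is testable without any
# experimental download. All randomness flows through an explicit seed and
# the ambient RNG state is restored afterwards.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort("`seed` is mandatory and must be a single finite number.")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate biphasic bead displacement traces
#'
#' Emulates the bead response to localised indentation: a fast phase
#' completing within ~0.3 s (surface-tension-mediated, simultaneous at all
#' distances) plus a slow exponential phase with a distance-dependent
#' relaxation time \eqn{\tau_p(r)}, and nm-scale measurement noise:
#' \deqn{z(t) = A_{fast}(r)\,\min(t/t_{fast}, 1)
#'   + A_{slow}(r)\,(1 - e^{-t/\tau_p(r)}) + \epsilon.}
#' Beads closer than `sign_switch_um` to the stimulus move down, beads
#' further away move up. Default amplitudes are order-of-magnitude
#' placeholders (hundreds of nm, decaying with distance), not measured
#' values.
#'
#' @param distances Bead distances from the stimulus, um.
#' @param seed RNG seed (mandatory).
#' @param fast_amplitude,slow_amplitude,tau_p Functions of distance r (um)
#'   returning amplitude (um, unsigned) and relaxation time (s);
#'   `tau_p` is non-decreasing in r by default.
#' @param sigma_nm Additive Gaussian noise, nm.
#' @param sign_switch_um Distance at which the displacement sign flips
#'   from downward to upward.
#' @param t_end,dt Trace duration and sampling interval, s.
#' @param fast_time Completion time of the fast phase, s (< 0.3).
#' @return A tibble with `trace_id`, `dx_um`, `t_s`, `z_um`, plus the
#'   ground-truth columns `tau_p_true_s`, `A_fast_um`, `A_slow_um`.
#' @export
gen_biphasic_traces <- function(distances, seed,
                                fast_amplitude = function(r) 0.25 * exp(-r / 15),
                                slow_amplitude = function(r) 0.35 * exp(-r / 15),
                                tau_p = function(r) 0.5 + 0.2 * r,
                                sigma_nm = 5, sign_switch_um = 6,
                                t_end = NULL, dt = 0.05, fast_time = 0.2) {
  stopifnot(all(distances > 0), sigma_nm >= 0, fast_time < 0.3)
  taus <- tau_p(distances)
  if (any(taus <= 0)) abort("tau_p(r) must be positive.")
  if (is.null(t_end)) t_end <- max(5, 4 * max(taus))
  with_seed(seed, {
    purrr::map_dfr(seq_along(distances), function(i) {
      r <- distances[i]
      s <- if (r < sign_switch_um) -1 else 1
      tt <- seq(0, t_end, by = dt)
      z <- s * fast_amplitude(r) * pmin(tt / fast_time, 1) +
        s * slow_amplitude(r) * (1 - exp(-tt / taus[i])) +
        rnorm(length(tt), sd = sigma_nm * 1e-3)
      z <- z - z[1]
      tibble(trace_id = i, dx_um = r, t_s = tt, z_um = z,
             tau_p_true_s = taus[i],
             A_fast_um = s * fast_amplitude(r),
             A_slow_um = s * slow_amplitude(r))
    })
  })
}

#' Generate injection propagation traces
#'
#' Bead traces after a pressure step through a pipette: no movement until
#' the fluid front arrives after a distance-dependent time lag, then a
#' saturating rise. The front model is linear in distance by default
#' (constant propagation velocity, the experimental observation), with a
#' diffusive quadratic alternative for sensitivity analyses.
#'
#' @param distances Bead distances from the pipette, um.
#' @param seed RNG seed (mandatory).
#' @param velocity_um_s Front velocity for the linear model, um/s.
#' @param D_front_um2_s Effective diffusivity for the quadratic model
#'   (lag = dx^2 / D), um^2/s.
#' @param front_model `"linear"` or `"quadratic"`.
#' @param amplitude Function of distance giving the plateau displacement, um.
#' @param tau_rise Rise time after front arrival, s.
#' @param sigma_nm Additive Gaussian noise, nm.
#' @param t_end,dt Duration and sampling interval, s.
#' @return Tibble with `trace_id`, `dx_um`, `t_s`, `z_um`, `dt_true_s`.
#' @export
gen_injection_traces <- function(distances, seed, velocity_um_s = 10,
                                 D_front_um2_s = 100,
                                 front_model = c("linear", "quadratic"),
                                 amplitude = function(r) 0.6 * exp(-r / 20),
                                 tau_rise = 0.5, sigma_nm = 5,
                                 t_end = 6, dt = 0.05) {
  front_model <- match.arg(front_model)
  stopifnot(all(distances > 0), sigma_nm >= 0)
  lags <- switch(front_model,
    linear = distances / velocity_um_s,
    quadratic = distances^2 / D_front_um2_s)
  with_seed(seed, {
    purrr::map_dfr(seq_along(distances), function(i) {
      r <- distances[i]
      tt <- seq(0, t_end, by = dt)
      z <- ifelse(tt <= lags[i], 0,
                  amplitude(r) * (1 - exp(-(tt - lags[i]) / tau_rise))) +
        rnorm(length(tt), sd = sigma_nm * 1e-3)
      z <- z - z[1]
      tibble(trace_id = i, dx_um = r, t_s = tt, z_um = z,
             dt_true_s = lags[i])
    })
  })
}

#' Generate a Darcy pressure-step dataset
#'
#' Produces records of (length scale, time lag, pressure step) with the
#' structure assumed by [darcy_fit()]. Under the default `"local_gradient"`
#' model the lag is \eqn{\delta t = \Delta x^2/(k\,\Delta P)}, so the
#' velocity and gradient estimates satisfy Darcy's law record by record and
#' [darcy_fit()] recovers `k` exactly at zero noise. The
#' `"constant_velocity"` alternative makes the lag linear in distance
#' (front crossing the whole cell at one velocity), which is what the
#' experiments observe; with it the local-gradient estimator is only
#' approximately unbiased.
#'
#' @param k Hydraulic permeability, um^2/(Pa s).
#' @param dP Pressure steps, Pa (recycled against `dx`).
#' @param dx Length scales, um.
#' @param seed RNG seed (mandatory).
#' @param noise Multiplicative log-normal noise level on the lags
#'   (e.g. 0.2 for ~20%).
#' @param front_model `"local_gradient"` or `"constant_velocity"`.
#' @param L_ref Reference gradient length for the constant-velocity model,
#'   um (default: mean of `dx`).
#' @return Tibble with `length_um`, `dP_Pa`, `dt_s`, `dt_true_s`, `cell_id`.
#' @examples
#' d <- gen_darcy_dataset(k = 0.125, dP = rep(c(300, 500, 800), 4),
#'                        dx = rep(c(4, 8, 12, 16), 3), seed = 1, noise = 0)
#' darcy_fit(d)$k_um2_Pa_s   # 0.125
#' @export
gen_darcy_dataset <- function(k, dP, dx, seed, noise = 0.2,
                              front_model = c("local_gradient",
                                              "constant_velocity"),
                              L_ref = NULL) {
  front_model <- match.arg(front_model)
  stopifnot(k > 0, all(dP > 0), all(dx > 0), noise >= 0)
  n <- max(length(dP), length(dx))
  dP <- rep_len(dP, n); dx <- rep_len(dx, n)
  dt_true <- switch(front_model,
    local_gradient = dx^2 / (k * dP),
    constant_velocity = {
      if (is.null(L_ref)) L_ref <- mean(dx)
      dx * L_ref / (k * dP)
    })
  with_seed(seed, {
    fac <- if (noise > 0) exp(rnorm(n, sd = noise)) else rep(1, n)
    tibble(length_um = dx, dP_Pa = dP, dt_s = dt_true * fac,
           dt_true_s = dt_true, cell_id = seq_len(n))
  })
}

#' Generate metaphase diameter time courses under pressure steps
#'
#' A rounded (metaphase) cell in fluidic contact with a pipette: after a
#' pressure step \eqn{\Delta P} the diameter stays flat for a hyperbolic
#' time lag \eqn{\delta t = c/\Delta P}, then rises linearly at a
#' pressure-dependent rate. Defaults give replicate structure (3 cells per
#' pressure).
#'
#' @param dP Pressure steps, Pa.
#' @param seed RNG seed (mandatory).
#' @param baseline_d Baseline diameter, um.
#' @param c_Pa_s Hyperbolic lag constant: \eqn{\delta t = c/\Delta P}, s Pa.
#' @param rate_per_Pa Diameter growth rate per unit pressure, um/(s Pa).
#' @param replicates Cells per pressure.
#' @param noise Multiplicative noise on lag and rate (log-normal level).
#' @param sigma_um Additive Gaussian noise on the diameter samples, um.
#' @param t_end,dt Duration and sampling interval, s.
#' @return Tibble with `dP_Pa`, `replicate`, `t_s`, `d_um`, `dt_true_s`.
#' @export
gen_metaphase_diameter <- function(dP, seed, baseline_d = 20, c_Pa_s = 200,
                                   rate_per_Pa = 1e-3, replicates = 3,
                                   noise = 0.1, sigma_um = 0.02,
                                   t_end = 8, dt = 0.05) {
  stopifnot(all(dP > 0), c_Pa_s > 0, rate_per_Pa > 0, noise >= 0)
  with_seed(seed, {
    purrr::map_dfr(seq_along(dP), function(i) {
      purrr::map_dfr(seq_len(replicates), function(rep_i) {
        lag <- c_Pa_s / dP[i] * (if (noise > 0) exp(rnorm(1, sd = noise)) else 1)
        rate <- rate_per_Pa * dP[i] *
          (if (noise > 0) exp(rnorm(1, sd = noise)) else 1)
        tt <- seq(0, t_end, by = dt)
        d <- baseline_d + pmax(0, tt - lag) * rate +
          rnorm(length(tt), sd = sigma_um)
        tibble(dP_Pa = dP[i], replicate = rep_i, t_s = tt, d_um = d,
               dt_true_s = lag)
      })
    })
  })
}

#' Onset lags from diameter time courses
#'
#' Reduces [gen_metaphase_diameter()]-style series (or measured ones) to
#' one onset lag per curve by thresholding the diameter increase above
#' baseline, ready for [hyperbolic_lag_fit()].
#'
#' @param series Tibble with `dP_Pa`, `replicate`, `t_s`, `d_um`.
#' @param threshold_um Diameter increase defining onset, um.
#' @return Tibble with `dP_Pa`, `replicate`, `dt_s`.
#' @export
diameter_onset_lags <- function(series, threshold_um = 0.05) {
  series |>
    dplyr::group_by(.data$dP_Pa, .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      d0 <- mean(df$d_um[df$t_s <= df$t_s[1] + 3 * diff(df$t_s[1:2])])
      lag <- time_lag(tibble(t_s = df$t_s, z_um = df$d_um - d0),
                      rule = "absolute", threshold = threshold_um)
      tibble(dt_s = lag)
    }) |>
    dplyr::ungroup()
}
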