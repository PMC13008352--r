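# Estimators converting bead traces and pressure-step datasets into the
# derived quantities of the analysis: onset time lags, slow-phase
# relaxation times, and hydraulic permeability via Darcy's law.

#' Time lag of a bead displacement trace
#'
#' First crossing time of a displacement threshold, by linear interpolation
#' between samples. Two threshold rules are in experimental use and both
#' are explicit here: `"absolute"` uses a fixed displacement (0.1 um by
#' default, the experimental convention), `"fraction"` uses a fraction of
#' the steady-state displacement (10% by default, the simulation
#' convention). The steady-state displacement is the trace's final value.
#'
#' @param trace A data frame with columns `t_s` and `z_um` (displacement
#'   from baseline; `z_um[1]` should be 0).
#' @param rule `"absolute"` or `"fraction"`; never defaulted silently.
#' @param threshold Threshold value: um for `"absolute"`, a fraction for
#'   `"fraction"`.
#' @return The crossing time in s, or `NA_real_` if the trace never
#'   crosses (distinct from a zero lag).
#' @examples
#' tr <- tibble::tibble(t_s = 0:10, z_um = 0.05 * (0:10))
#' time_lag(tr, rule = "absolute", threshold = 0.1)  # 2.0
#' @export
time_lag <- function(trace, rule = c("absolute", "fraction"),
                     threshold = NULL) {
  rule <- match.arg(rule)
  if (is.null(threshold)) threshold <- 0.1   # 0.1 um, or 10% of steady state
  check_trace(trace)
  z <- trace$z_um; t <- trace$t_s
  thr <- switch(rule,
    absolute = threshold,
    fraction = threshold * z[length(z)])
  if (thr == 0) return(0)
  s <- sign(thr)
  zz <- s * z; thr <- s * thr       # handle downward traces symmetrically
  above <- zz >= thr
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(t[1])
  t[i - 1] + (thr - zz[i - 1]) / (zz[i] - zz[i - 1]) * (t[i] - t[i - 1])
}

check_trace <- function(trace) {
  if (!all(c("t_s", "z_um") %in% names(trace)))
    abort("A trace needs columns `t_s` and `z_um`.")
  if (any(diff(trace$t_s) <= 0))
    abort("Trace time must be strictly increasing.")
  invisible(trace)
}

#' Hydraulic permeability by Darcy regression on pressure-step data
#'
#' For each record the flow velocity is estimated as
#' \eqn{v = \Delta x / \delta t} (length scale over onset time lag) and the
#' pressure gradient as \eqn{g = \Delta P / \Delta x}; Darcy's law
#' \eqn{v = k g} is then fit as a through-origin least-squares slope
#' (Darcy's law has no offset). The coefficient of determination of the
#' free-intercept fit is reported alongside for comparability with
#' experimental reports.
#'
#' @param data A data frame with columns `length_um` (bead distance or cell
#'   diameter), `dt_s` (time lag) and `dP_Pa` (pressure step). Records with
#'   non-positive `dt_s` are rejected and counted.
#' @return A one-row tibble: `k_um2_Pa_s`, `r_squared` (free-intercept),
#'   `intercept_um_s`, `n_used`, `n_rejected`. Multiply `k_um2_Pa_s` by
#'   1e-12 for SI m^2/(Pa s).
#' @examples
#' d <- tibble::tibble(length_um = c(5, 10, 15), dP_Pa = c(500, 500, 500))
#' d$dt_s <- d$length_um^2 / (0.125 * d$dP_Pa)
#' darcy_fit(d)   # k = 0.125
#' @export
darcy_fit <- function(data) {
  need <- c("length_um", "dt_s", "dP_Pa")
  if (!all(need %in% names(data)))
    abort("`data` needs columns length_um, dt_s, dP_Pa.")
  bad <- !is.finite(data$dt_s) | data$dt_s <= 0 |
    data$length_um <= 0 | data$dP_Pa <= 0
  n_rej <- sum(bad)
  d <- data[!bad, ]
  if (nrow(d) < 3L) abort("Need at least 3 usable records.")
  v <- d$length_um / d$dt_s
  g <- d$dP_Pa / d$length_um
  k <- sum(v * g) / sum(g^2)
  fit <- lm(v ~ g)
  tibble(k_um2_Pa_s = k,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         intercept_um_s = unname(coef(fit)[1]),
         n_used = nrow(d), n_rejected = n_rej)
}

#' Hyperbolic fit of time lag versus pressure step
#'
#' Least-squares fit of \eqn{\delta t = c / \Delta P}, the relation
#' expected when a fixed propagation distance is crossed at a Darcy
#' velocity proportional to the applied pressure.
#'
#' @param data A data frame with columns `dt_s` and `dP_Pa` (>= 3 distinct
#'   pressures, all positive).
#' @return A one-row tibble: `c_Pa_s`, `rmse_s` (fit residual) and
#'   `rel_rmse` (residual relative to the mean lag; near 1 flags a misfit
#'   such as pressure-independent lags).
#' @examples
#' d <- tibble::tibble(dP_Pa = c(100, 200, 400), dt_s = 200 / c(100, 200, 400))
#' hyperbolic_lag_fit(d)   # c = 200
#' @export
hyperbolic_lag_fit <- function(data) {
  if (!all(c("dt_s", "dP_Pa") %in% names(data)))
    abort("`data` needs columns dt_s and dP_Pa.")
  if (any(data$dP_Pa <= 0)) abort("All pressure steps must be positive.")
  if (length(unique(data$dP_Pa)) < 3L)
    abort("Need at least 3 distinct pressure steps.")
  x <- 1 / data$dP_Pa
  cc <- sum(data$dt_s * x) / sum(x^2)
  res <- data$dt_s - cc * x
  rmse <- sqrt(mean(res^2))
  tibble(c_Pa_s = cc, rmse_s = rmse,
         rel_rmse = rmse / mean(abs(data$dt_s)))
}

#' Slow-phase relaxation time of a biphasic bead trace
#'
#' The bead response to localised indentation is biphasic: a fast phase
#' (complete within ~0.3 s) followed by a slow exponential approach to the
#' final displacement with characteristic time \eqn{\tau_p}. This fits
#' \deqn{z(t) = z_\infty + (z_{split} - z_\infty) e^{-(t - t_{split})/\tau_p}}
#' to the post-split segment by nonlinear least squares. The phase split
#' time is a fixed, explicit argument (default 0.3 s) rather than an
#' automatic changepoint.
#'
#' @param trace A data frame with `t_s`, `z_um`.
#' @param phase_split_time Start of the slow phase, s.
#' @param tau_init Optional initial guess for \eqn{\tau_p}, s.
#' @return A one-row tibble: `tau_p_s`, `z_inf_um`, `z_split_um`,
#'   `rmse_um`, `converged`.
#' @export
tau_p_fit <- function(trace, phase_split_time = 0.3, tau_init = NULL) {
  check_trace(trace)
  seg <- trace[trace$t_s >= phase_split_time, ]
  if (nrow(seg) < 4L)
    abort("Too few samples after the phase split to fit a relaxation time.")
  t0 <- seg$t_s[1]
  z0 <- seg$z_um[1]
  zinf0 <- mean(tail(seg$z_um, max(3L, nrow(seg) %/% 10L)))
  span <- max(seg$t_s) - t0
  if (is.null(tau_init)) {
    # crude guess: time to cover 63% of the remaining relaxation
    gap <- abs(seg$z_um - (z0 + 0.632 * (zinf0 - z0)))
    tau_init <- max(seg$t_s[which.min(gap)] - t0, span / 50)
  }
  dat <- data.frame(tt = seg$t_s - t0, z = seg$z_um)
  fit <- tryCatch(
    minpack.lm::nlsLM(z ~ zinf + (zs - zinf) * exp(-tt / tau),
                      data = dat,
                      start = list(zinf = zinf0, zs = z0, tau = tau_init),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    abort("Relaxation-time fit did not converge (inspect the trace).")
  co <- coef(fit)
  tibble(tau_p_s = unname(co["tau"]), z_inf_um = unname(co["zinf"]),
         z_split_um = unname(co["zs"]),
         rmse_um = sqrt(mean(stats::residuals(fit)^2)),
         converged = fit$convInfo$isConv)
}
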