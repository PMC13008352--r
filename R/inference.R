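# Two-stage inference of (E, D) by matching forward simulations to
# displacement observations: a log-spaced grid scan for a first
# approximation, then bounded derivative-free local refinement. The
# forward model is smooth but gradient-free, and stiffness/mobility enter
# the assembled system linearly, so one mesh assembly serves every
# objective evaluation.

new_poro_fit <- function(E, D, objective, trace, convergence, grid,
                         warnings = character(), meta = list()) {
  structure(list(E_Pa = E, D_um2_s = D, objective = objective,
                 trace = trace, convergence = convergence, grid = grid,
                 warnings = warnings, meta = meta),
            class = "poro_fit")
}

#' @export
print.poro_fit <- function(x, ...) {
  cat(sprintf("<poro_fit> E = %.4g Pa, D = %.4g um^2/s, objective %.3e (%s)\n",
              x$E_Pa, x$D_um2_s, x$objective,
              if (x$convergence == 0) "converged" else "not converged"))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
tidy.poro_fit <- function(x, ...) {
  tibble(term = c("E_Pa", "D_um2_s"), estimate = c(x$E_Pa, x$D_um2_s))
}

#' @export
glance.poro_fit <- function(x, ...) {
  tibble(objective = x$objective, convergence = x$convergence,
         n_evaluations = nrow(x$trace),
         n_warnings = length(x$warnings))
}

check_init_bounds <- function(init, bounds) {
  if (!all(c("E", "D") %in% names(init)))
    abort("`init` must name E (Pa) and D (um^2/s).")
  if (is.null(bounds))
    bounds <- list(E = init[["E"]] * c(1 / 20, 20),
                   D = init[["D"]] * c(1 / 20, 20))
  for (nm in c("E", "D")) {
    b <- bounds[[nm]]
    if (any(b <= 0) || b[1] >= b[2])
      abort(sprintf("Bounds for %s must be positive and increasing.", nm))
    if (init[[nm]] < b[1] || init[[nm]] > b[2])
      abort(sprintf("Initial guess for %s lies outside its bounds.", nm))
  }
  bounds
}

# normalised sum of squared residuals over one or more observed series;
# each series is scaled by its own max |observed| so displacement (um) and
# lag (s) observables mix without manual weights
series_objective <- function(pairs) {
  total <- 0
  for (p in pairs) {
    scale <- max(abs(p$obs))
    if (scale == 0) scale <- 1
    total <- total + mean(((p$sim - p$obs) / scale)^2)
  }
  total
}

# shared grid scan + Nelder-Mead refinement on log10 parameters
run_two_stage <- function(objective_fn, init, bounds, grid_n = 5,
                          reltol = 1e-9, maxit = 300) {
  evals <- new.env(parent = emptyenv())
  evals$log <- list()
  wrapped <- function(lp) {
    E <- 10^lp[1]; D <- 10^lp[2]
    if (E < bounds$E[1] || E > bounds$E[2] ||
        D < bounds$D[1] || D > bounds$D[2]) return(1e6)
    val <- objective_fn(E, D)
    evals$log[[length(evals$log) + 1L]] <- c(E = E, D = D, objective = val)
    val
  }
  gE <- 10^seq(log10(bounds$E[1]), log10(bounds$E[2]), length.out = grid_n)
  gD <- 10^seq(log10(bounds$D[1]), log10(bounds$D[2]), length.out = grid_n)
  grid <- tidyr::expand_grid(E = gE, D = gD)
  grid$objective <- purrr::map2_dbl(grid$E, grid$D,
                                    function(E, D) wrapped(log10(c(E, D))))
  best <- grid[which.min(grid$objective), ]
  # include the user's init as a candidate start
  init_obj <- wrapped(log10(c(init[["E"]], init[["D"]])))
  start <- if (init_obj < best$objective) c(init[["E"]], init[["D"]])
           else c(best$E, best$D)
  opt <- optim(log10(start), wrapped, method = "Nelder-Mead",
               control = list(reltol = reltol, maxit = maxit))
  trace <- dplyr::bind_rows(lapply(evals$log, function(v) as_tibble(as.list(v))))
  list(E = 10^opt$par[1], D = 10^opt$par[2], objective = opt$value,
       convergence = opt$convergence, grid = grid, trace = trace)
}

#' Fit (E, D) to indentation observables
#'
#' Matches forward simulations of the ramp-and-hold indentation protocol
#' to an observed steady-state surface displacement profile and
#' (optionally, but required when `D` is free) a force-relaxation
#' timecourse. The modulus governs amplitude, the diffusion constant
#' governs kinetics, so a steady profile alone cannot identify `D`.
#' Objective: sum of per-series normalised squared residuals. Stage 1
#' scans a log-spaced grid over the bounds; stage 2 refines with
#' Nelder-Mead on log parameters. Deterministic: identical inputs give
#' identical results.
#'
#' @param observed List with `profile` (tibble `r_um`, `u_z_um`) and
#'   optionally `force` (tibble `t_s`, `force_nN`).
#' @param geometry,protocol Disk geometry and [indentation_protocol()]
#'   describing the experiment.
#' @param init Named vector `c(E = , D = )`, Pa and um^2/s.
#' @param bounds Named list of c(lo, hi) per parameter; default init x
#'   [1/20, 20].
#' @param nu Fixed drained Poisson ratio.
#' @param resolution Coarse fitting mesh resolution, um.
#' @param verify_resolution Optional finer resolution for a single
#'   verification solve at the optimum; a >5% output discrepancy adds a
#'   warning to the result.
#' @param grid_n Grid points per parameter in stage 1.
#' @return A `poro_fit`; see [tidy.poro_fit()] / [glance.poro_fit()].
#' @export
fit_indentation <- function(observed, geometry, protocol, init,
                            bounds = NULL, nu = 0.3, resolution = 2.5,
                            verify_resolution = NULL, grid_n = 5) {
  if (is.null(observed$profile) || nrow(observed$profile) < 4L)
    abort("Need a steady-state profile with at least 4 distances.")
  has_force <- !is.null(observed$force)
  if (!has_force)
    abort(paste("D is not identifiable from a steady-state profile alone;",
                "supply a force-relaxation timecourse in `observed$force`."))
  bounds <- check_init_bounds(init, bounds)
  mesh <- build_mesh(geometry, resolution)
  cache <- NULL
  forward <- function(E, D) {
    mats <- material_region("cytoplasm", E = E, nu = nu, D = D)
    resp <- simulate_indentation(geometry, mats, protocol, mesh = mesh,
                                 cache = cache)
    cache <<- attr(resp$solution, "cache")
    resp
  }
  obj <- function(E, D) {
    resp <- forward(E, D)
    pairs <- list(list(obs = observed$profile$u_z_um,
                       sim = approx(resp$profile$r_um, resp$profile$u_z_um,
                                    xout = observed$profile$r_um,
                                    rule = 2)$y))
    if (has_force) {
      sim_f <- approx(resp$force$t_s, resp$force$force_nN,
                      xout = observed$force$t_s, rule = 2)$y
      pairs <- c(pairs, list(list(obs = observed$force$force_nN, sim = sim_f)))
    }
    series_objective(pairs)
  }
  res <- run_two_stage(obj, init, bounds, grid_n = grid_n)
  warnings <- character()
  if (!is.null(verify_resolution)) {
    warnings <- c(warnings,
                  verify_fine_mesh(geometry, protocol, res, nu,
                                   verify_resolution, observed))
  }
  new_poro_fit(res$E, res$D, res$objective, res$trace, res$convergence,
               res$grid, warnings,
               meta = list(scenario = "indentation", nu = nu,
                           resolution = resolution, bounds = bounds,
                           init = init))
}

verify_fine_mesh <- function(geometry, protocol, res, nu, resolution,
                             observed) {
  mats <- material_region("cytoplasm", E = res$E, nu = nu, D = res$D)
  fine <- simulate_indentation(geometry, mats, protocol,
                               resolution = resolution)
  coarse_prof <- observed$profile
  fine_prof <- approx(fine$profile$r_um, fine$profile$u_z_um,
                      xout = coarse_prof$r_um, rule = 2)$y
  rel <- max(abs(fine_prof - coarse_prof$u_z_um)) /
    max(abs(coarse_prof$u_z_um))
  if (rel > 0.05)
    sprintf("fine-mesh verification differs by %.1f%% from the fitted observables",
            100 * rel)
  else character()
}

#' Fit (E, D) to microinjection observables
#'
#' Matches forward simulations of the microinjection protocol (effective
#' pressure fixed, 500 Pa by default per the experimental estimate) to
#' per-probe vertical displacements at an observation time (2 s, the end
#' of the pressure ramp) plus onset time lags. Two-stage optimisation as
#' in [fit_indentation()]. With the displacement amplitude scaling as
#' P_eff/E in the linear regime, an error in the fixed P_eff propagates
#' into E nearly proportionally (E and P_eff are not separately
#' identifiable from displacements alone); D is set by the lag kinetics.
#'
#' @param observed Tibble with `probe_um`, `u_z_um` (displacement at
#'   `t_obs`) and optionally `dt_s` (time lags); >= 4 probes.
#' @param geometry An `elliptical_cap` [scenario_geometry()].
#' @param protocol Injection [pressure_protocol()] (carries the fixed
#'   P_eff).
#' @param init,bounds,nu,resolution,grid_n As in [fit_indentation()].
#' @param t_obs Observation time for displacements, s.
#' @return A `poro_fit`.
#' @export
fit_injection <- function(observed, geometry, protocol, init, bounds = NULL,
                          nu = 0.3, resolution = 1.5, grid_n = 5,
                          t_obs = 2) {
  need <- c("probe_um", "u_z_um")
  if (!all(need %in% names(observed)))
    abort("`observed` needs columns probe_um and u_z_um.")
  if (nrow(observed) < 4L)
    abort("Under-determined: need at least 4 probes.")
  warnings <- character()
  if (length(unique(observed$probe_um)) == 1L)
    abort("All probes coincide; the profile shape is unidentifiable.")
  if (sd(observed$probe_um) / mean(observed$probe_um) < 0.1)
    warnings <- c(warnings,
                  "probes nearly equidistant from the source; fit may be ill-conditioned")
  has_lags <- "dt_s" %in% names(observed)
  bounds <- check_init_bounds(init, bounds)
  mesh <- build_mesh(geometry, resolution)
  cache <- NULL
  probes <- observed$probe_um
  obj <- function(E, D) {
    mats <- material_region("cytoplasm", E = E, nu = nu, D = D)
    resp <- simulate_injection(geometry, mats, protocol, probes = probes,
                               mesh = mesh, cache = cache)
    cache <<- attr(resp$solution, "cache")
    at_t <- resp$probes |>
      dplyr::group_by(.data$probe_um) |>
      dplyr::summarise(u = approx(.data$t_s, .data$u_z_um, xout = t_obs,
                                  rule = 2)$y, .groups = "drop")
    sim_u <- at_t$u[match(probes, at_t$probe_um)]
    pairs <- list(list(obs = observed$u_z_um, sim = sim_u))
    if (has_lags) {
      sim_lag <- resp$time_lags$dt_s[match(probes, resp$time_lags$probe_um)]
      ok <- is.finite(observed$dt_s) & is.finite(sim_lag)
      if (any(ok))
        pairs <- c(pairs, list(list(obs = observed$dt_s[ok],
                                    sim = sim_lag[ok])))
    }
    series_objective(pairs)
  }
  res <- run_two_stage(obj, init, bounds, grid_n = grid_n)
  new_poro_fit(res$E, res$D, res$objective, res$trace, res$convergence,
               res$grid, warnings,
               meta = list(scenario = "injection", nu = nu,
                           resolution = resolution, bounds = bounds,
                           init = init, P_eff = protocol$P_eff,
                           t_obs = t_obs))
}
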