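# The three in-silico cell experiments: localised indentation of a disk,
# fluid microinjection into an elliptical cap, and localised
# depressurisation through a low-permeability cortex layer.

#' Indentation protocol
#'
#' Ramp-and-hold indentation by a rigid spherical indenter. The contact is
#' simplified to a prescribed vertical displacement over the geometric
#' contact patch \eqn{a = \sqrt{R\delta}} (frictionless, impermeable).
#'
#' @param depth Indentation depth \eqn{\delta}, um (>= 0).
#' @param ramp_time Ramp duration, s; the experimental protocol indents
#'   near-instantaneously (~0.01 s).
#' @param hold_time Hold duration after the ramp, s.
#' @param indenter_radius Spherical indenter radius R, um.
#' @return A list of class `indentation_protocol`.
#' @export
indentation_protocol <- function(depth = 2, ramp_time = 0.01, hold_time = 5,
                                 indenter_radius = 2) {
  stopifnot(depth >= 0, ramp_time > 0, hold_time > 0, indenter_radius > 0)
  structure(list(depth = depth, ramp_time = ramp_time, hold_time = hold_time,
                 indenter_radius = indenter_radius),
            class = "indentation_protocol")
}

#' Pressure protocol for microinjection / depressurisation
#'
#' A micropipette in fluidic contact with the top surface applies `P_app`
#' against the cell's internal pressure `P_in`; the effective pressure
#' \eqn{P_{eff} = P_{app} - P_{in}} drives injection (positive) or release
#' (negative).
#'
#' @param P_in Internal (baseline) pressure, Pa.
#' @param P_app Applied pipette pressure, Pa.
#' @param ramp_time Pressure ramp duration, s.
#' @param duration Total simulated time, s.
#' @param mode `"injection"` or `"release"`; must agree with the sign of
#'   \eqn{P_{app} - P_{in}}.
#' @return A list of class `pressure_protocol` (with `P_eff` precomputed).
#' @export
pressure_protocol <- function(P_in = 0, P_app, ramp_time = 2, duration = 8,
                              mode = NULL) {
  stopifnot(ramp_time >= 0, duration > ramp_time)
  P_eff <- P_app - P_in
  if (is.null(mode)) mode <- if (P_eff > 0) "injection" else "release"
  if (mode == "injection" && P_eff <= 0)
    abort("Injection requires P_app > P_in.")
  if (mode == "release" && P_eff >= 0)
    abort("Release requires P_app < P_in.")
  structure(list(P_in = P_in, P_app = P_app, P_eff = P_eff,
                 ramp_time = ramp_time, duration = duration, mode = mode),
            class = "pressure_protocol")
}

new_surface_response <- function(scenario, profile, probes = NULL,
                                 force = NULL, pressure = NULL,
                                 time_lags = NULL, solution = NULL,
                                 steady = NA, meta = list()) {
  structure(list(scenario = scenario, profile = profile, probes = probes,
                 force = force, pressure = pressure, time_lags = time_lags,
                 solution = solution, steady = steady, meta = meta),
            class = "surface_response")
}

#' @export
print.surface_response <- function(x, ...) {
  cat(sprintf("<surface_response> %s; steady state: %s\n", x$scenario,
              if (isTRUE(x$steady)) "reached" else "not reached"))
  if (!is.null(x$profile))
    cat(sprintf("  surface profile: %d points, u_z range [%.4g, %.4g] um\n",
                nrow(x$profile), min(x$profile$u_z_um), max(x$profile$u_z_um)))
  if (!is.null(x$time_lags))
    cat(sprintf("  time lags at %d probes\n", nrow(x$time_lags)))
  invisible(x)
}

# relative change of the surface profile over the trailing 5% of the window
steady_reached <- function(solution, window = 0.05, rel_tol = 0.01) {
  tmax <- max(solution$times)
  a <- surface_displacement(solution, time = tmax * (1 - window))
  b <- surface_displacement(solution, time = tmax)
  scale <- max(abs(b$u_z_um))
  if (scale == 0) return(TRUE)
  max(abs(b$u_z_um - a$u_z_um)) / scale < rel_tol
}

#' Simulate localised indentation of a cell-like poroelastic disk
#'
#' Ramp-and-hold indentation of a cylindrical disk: no-slip base, free
#' impermeable side, drained top surface (zero pore pressure) except under
#' the impermeable indenter. Returns the hold-phase force relaxation and
#' the steady-state surface displacement profile; the profile typically
#' shows downward motion near the contact and upward motion further out.
#'
#' @param geometry A disk [scenario_geometry()].
#' @param materials A [material_region()] / [material_set()] covering the
#'   mesh regions.
#' @param protocol An [indentation_protocol()].
#' @param probes Optional radial probe distances for displacement
#'   timecourses, um.
#' @param resolution Mesh resolution, um.
#' @param mesh,cache Optional prebuilt mesh and assembly cache (reused
#'   across fits).
#' @param n_ramp Ramp steps.
#' @return A `surface_response` with `profile`, `force`, optional `probes`.
#' @export
simulate_indentation <- function(geometry, materials, protocol,
                                 probes = NULL, resolution = 2,
                                 mesh = NULL, cache = NULL, n_ramp = 5) {
  stopifnot(inherits(protocol, "indentation_protocol"))
  if (geometry$shape != "disk")
    abort("Indentation runs on the disk geometry.")
  if (protocol$depth > geometry$thickness / 2)
    abort("Indentation depth exceeds half the thickness (small-strain validity).")
  a <- sqrt(protocol$indenter_radius * max(protocol$depth, 1e-12))
  if (a >= geometry$radius)
    abort("Contact patch exceeds the domain radius.")
  if (is.null(mesh)) mesh <- build_mesh(geometry, resolution)
  a_eff <- max(a, min_contact_radius(mesh))
  bcs <- boundary_spec(
    mech = list(bottom = "fixed", side = "free",
                surface = list(type = "indent", depth = protocol$depth,
                               ramp_time = protocol$ramp_time,
                               radius = a_eff)),
    hyd = list(surface = list(type = "pressure", value = 0,
                              where = "outside_radius", radius = a_eff)))
  run_scenario("indentation", mesh, materials, bcs,
               ramp_time = protocol$ramp_time,
               t_end = protocol$ramp_time + protocol$hold_time,
               n_ramp = n_ramp, probes = probes, cache = cache,
               with_force = TRUE,
               meta = list(contact_radius = a_eff, protocol = protocol))
}

min_contact_radius <- function(mesh) {
  sn <- boundary_nodes(mesh, "surface")
  r <- sort(mesh$nodes[sn, 1])
  r[3]  # at least two elements' worth of constrained surface nodes
}

#' Simulate fluid microinjection into an adherent cell
#'
#' An elliptical-cap cell attached to a substrate receives fluid through a
#' pipette contact at the apex: the effective pressure is ramped at the
#' contact patch while the rest of the boundary is impermeable (membrane
#' water exchange is negligible on the injection time-scale). Per-probe
#' vertical displacement traces are reported along with time lags by the
#' 10%-of-steady-state rule.
#'
#' @param geometry An `elliptical_cap` [scenario_geometry()].
#' @param materials Materials covering the mesh regions.
#' @param protocol A [pressure_protocol()] (release mode is allowed and
#'   yields suction through the same contact).
#' @param probes Radial probe distances from the pipette, um.
#' @param resolution Mesh resolution, um.
#' @param mesh,cache Optional prebuilt mesh and assembly cache.
#' @param n_ramp Ramp steps.
#' @return A `surface_response` with `probes`, `profile` and `time_lags`.
#' @export
simulate_injection <- function(geometry, materials, protocol,
                               probes = c(3, 6, 9, 12, 15), resolution = 1.5,
                               mesh = NULL, cache = NULL, n_ramp = 16) {
  stopifnot(inherits(protocol, "pressure_protocol"))
  if (geometry$shape != "elliptical_cap")
    abort("Microinjection runs on the elliptical_cap geometry.")
  if (is.null(mesh)) mesh <- build_mesh(geometry, resolution)
  bcs <- boundary_spec(
    mech = list(bottom = "fixed", side = "free"),
    hyd = list(surface = list(type = "pressure", value = protocol$P_eff,
                              ramp_time = protocol$ramp_time,
                              where = "within_radius",
                              radius = geometry$contact_radius)))
  resp <- run_scenario("injection", mesh, materials, bcs,
                       ramp_time = protocol$ramp_time,
                       t_end = protocol$duration, n_ramp = n_ramp,
                       probes = probes, cache = cache,
                       meta = list(protocol = protocol))
  if (!is.null(resp$probes)) {
    resp$time_lags <- resp$probes |>
      dplyr::group_by(.data$probe_um) |>
      dplyr::group_modify(function(df, key) {
        tibble(dt_s = time_lag(tibble(t_s = df$t_s, z_um = df$u_z_um),
                               rule = "fraction", threshold = 0.10))
      }) |>
      dplyr::ungroup()
  }
  resp
}

#' Simulate localised depressurisation through a cortex-bounded cell
#'
#' A two-layer cell (cytoplasm wrapped in a thin low-permeability cortex)
#' is depressurised through a small sink at the apex of the surface; the
#' remainder of the cortex outer boundary acts as a reservoir held at the
#' internal pressure (trans-membrane influx balancing the sink efflux). A
#' sweep over the cortex diffusion constant \eqn{D_1} reproduces how
#' membrane-cortex permeability sets the length-scale of the steady
#' intracellular pressure gradient.
#'
#' @param geometry An `elliptical_cap` [scenario_geometry()] with
#'   `cortex_thickness > 0`.
#' @param materials Two regions: `cytoplasm` and `cortex`.
#' @param protocol A release-mode [pressure_protocol()].
#' @param D1_sweep Cortex diffusion constants to sweep, um^2/s (default:
#'   the cortex material's own D).
#' @param resolution Mesh resolution, um.
#' @param profile_z Height of the reported pressure profile, um (default:
#'   mid-height of the cytoplasm).
#' @return A tibble with one row per `D1` value: `D1_um2_s`, the response
#'   object, and the 90% pressure-recovery distance `recovery_um`.
#' @export
simulate_depressurisation <- function(geometry, materials, protocol,
                                      D1_sweep = NULL, resolution = 1.5,
                                      profile_z = NULL) {
  stopifnot(inherits(protocol, "pressure_protocol"))
  if (protocol$mode != "release")
    abort("Depressurisation requires a release-mode protocol (P_app < P_in).")
  if (geometry$shape != "elliptical_cap" || geometry$cortex_thickness <= 0)
    abort("Depressurisation requires an elliptical_cap with a cortex layer.")
  if (!all(c("cytoplasm", "cortex") %in% materials$label))
    abort("Two material regions (cytoplasm and cortex) are required.")
  mesh <- build_mesh(geometry, resolution)
  # the pipette opening pierces the membrane-cortex layer: elements of the
  # cortex lying over the sink become cytoplasm so the sink couples to the
  # cell interior, not to the outside of the cortex
  ctr_r <- vapply(seq_len(nrow(mesh$conn)), function(e) {
    mean(mesh$nodes[mesh$conn[e, 1:4], 1])
  }, numeric(1))
  mesh$region[mesh$region == "cortex" &
                ctr_r <= geometry$contact_radius] <- "cytoplasm"
  cache <- NULL
  cortex <- materials[materials$label == "cortex", ]
  if (is.null(D1_sweep)) D1_sweep <- cortex$D_um2_s
  if (is.null(profile_z))
    profile_z <- (geometry$thickness - geometry$cortex_thickness) / 2
  bcs <- boundary_spec(
    mech = list(bottom = "fixed", side = "free"),
    hyd = list(surface = list(type = "pressure_split",
                              inner_value = protocol$P_eff, outer_value = 0,
                              radius = geometry$contact_radius,
                              ramp_time = protocol$ramp_time)))
  rows <- purrr::map(D1_sweep, function(D1) {
    mat1 <- material_region("cortex", E = cortex$E_Pa, nu = cortex$nu, D = D1)
    mats <- dplyr::bind_rows(materials[materials$label == "cytoplasm", ], mat1)
    resp <- run_scenario("depressurisation", mesh, mats, bcs,
                         ramp_time = protocol$ramp_time,
                         t_end = protocol$duration, n_ramp = 8,
                         probes = NULL, cache = cache,
                         meta = list(protocol = protocol, D1 = D1))
    cache <<- attr(resp$solution, "cache")
    pr <- pressure_profile(resp$solution, z = profile_z)
    pr$recovery <- 1 - pr$p_Pa / protocol$P_eff
    resp$pressure <- pr
    tibble(D1_um2_s = D1, response = list(resp),
           recovery_um = recovery_length(pr, 0.9))
  })
  dplyr::bind_rows(rows)
}

# smallest radius at which the pressure has recovered `frac` of the sink
# drawdown (linear interpolation along the profile)
recovery_length <- function(profile, frac = 0.9) {
  r <- profile$r_um; f <- profile$recovery
  if (all(f < frac)) return(NA_real_)
  i <- which(f >= frac)[1]
  if (i == 1) return(r[1])
  r[i - 1] + (frac - f[i - 1]) / (f[i] - f[i - 1]) * (r[i] - r[i - 1])
}

# shared scenario runner: builds the time grid, solves, extends once if the
# steady-state criterion is not met, and packages the observables
run_scenario <- function(scenario, mesh, materials, bcs, ramp_time, t_end,
                         n_ramp, probes, cache, with_force = FALSE,
                         meta = list()) {
  tg <- time_grid_ramp_hold(ramp_time, t_end, n_ramp = n_ramp)
  sol <- solve_transient(mesh, materials, bcs, tg, cache = cache)
  if (!steady_reached(sol)) {
    tg <- time_grid_ramp_hold(ramp_time, 2 * t_end, n_ramp = n_ramp)
    sol <- solve_transient(mesh, materials, bcs, tg,
                           cache = attr(sol, "cache"))
  }
  profile <- surface_displacement(sol)
  pr <- if (!is.null(probes)) probe_displacement(sol, probes)
  force <- if (with_force)
    tibble(t_s = sol$times, force_nN = sol$force)
  new_surface_response(scenario, profile = profile, probes = pr,
                       force = force, solution = sol,
                       steady = steady_reached(sol), meta = meta)
}
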