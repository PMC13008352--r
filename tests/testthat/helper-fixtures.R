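# Shared fixtures: the geometries, materials and protocols of the three
# in-silico experiments, at test-friendly mesh resolutions.

fix_disk <- function() scenario_geometry("disk", radius = 20, thickness = 20,
                                         indenter_radius = 2)

fix_cap <- function(cortex = 0)
  scenario_geometry("elliptical_cap", radius = 20, thickness = 4.5,
                    cortex_thickness = cortex, contact_radius = 1)

fix_cytoplasm <- function(E = 1200, D = 13)
  material_region("cytoplasm", E = E, nu = 0.3, D = D)

fix_column <- function(h = 20, r = 2) scenario_geometry("column", radius = r,
                                                        thickness = h)

# Terzaghi benchmark solve shared across solver tests (memoised per run)
fix_terzaghi_solution <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    geom <- fix_column()
    mesh <- build_mesh(geom, resolution = 0.75)
    mat <- material_region("cytoplasm", E = 1000, nu = 0.3, D = 10)
    bcs <- boundary_spec(
      mech = list(bottom = "roller_z", side = "roller_r",
                  surface = list(type = "traction", value = -100,
                                 ramp_time = 0)),
      hyd = list(surface = list(type = "pressure", value = 0)))
    tg <- unique(c(time_grid_ramp_hold(0, 2, dt0 = 0.01, growth = 1.15),
                   seq(2.25, 10, by = 0.25)))
    cached <<- solve_transient(mesh, mat, bcs, tg)
    cached
  }
})

# noiseless forward injection observables at the stated parameter point,
# on the given mesh resolution (self-consistency fixtures)
fix_injection_observed <- function(E = 1200, D = 13, P_eff = 500,
                                   probes = c(3, 6, 9, 12, 15),
                                   resolution = 1.5, t_obs = 2) {
  geom <- fix_cap()
  prot <- pressure_protocol(P_in = 0, P_app = P_eff, ramp_time = 2,
                            duration = 8)
  resp <- simulate_injection(geom, fix_cytoplasm(E, D), prot,
                             probes = probes, resolution = resolution)
  at_t <- resp$probes |>
    dplyr::group_by(probe_um) |>
    dplyr::summarise(u_z_um = stats::approx(t_s, u_z_um, xout = t_obs)$y,
                     .groups = "drop")
  list(observed = dplyr::left_join(at_t, resp$time_lags, by = "probe_um"),
       geometry = geom, protocol = prot, response = resp)
}
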