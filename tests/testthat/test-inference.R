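# Cheap structural and property tests of the two-stage fits; the full
# self-consistency recoveries at the published parameter points live in
# the acceptance suite.

test_that("identifiability and input validation are enforced", {
  geom <- fix_disk()
  prot <- indentation_protocol(depth = 2, hold_time = 4)
  prof <- tibble::tibble(r_um = c(3, 6, 9, 12), u_z_um = c(-0.5, -0.2, -0.1, -0.05))
  # D free with steady-state-only data is not identifiable
  expect_error(fit_indentation(list(profile = prof), geom, prot,
                               init = c(E = 1000, D = 10)),
               "identifiable")
  # init outside bounds
  expect_error(
    fit_indentation(list(profile = prof,
                         force = tibble::tibble(t_s = 0:3, force_nN = 4:1)),
                    geom, prot, init = c(E = 1000, D = 10),
                    bounds = list(E = c(2000, 4000), D = c(1, 100))),
    "outside")
  expect_error(
    fit_indentation(list(profile = prof[1:2, ],
                         force = tibble::tibble(t_s = 0:3, force_nN = 4:1)),
                    geom, prot, init = c(E = 1000, D = 10)),
    "at least 4")
  # injection: under-determined single probe
  cap <- fix_cap()
  iprot <- pressure_protocol(P_in = 0, P_app = 500)
  expect_error(fit_injection(tibble::tibble(probe_um = 5, u_z_um = 0.1),
                             cap, iprot, init = c(E = 1000, D = 10)),
               "4 probes")
  expect_error(fit_injection(tibble::tibble(probe_um = rep(5, 4),
                                            u_z_um = rep(0.1, 4)),
                             cap, iprot, init = c(E = 1000, D = 10)),
               "coincide")
})

test_that("injection fit is deterministic and self-consistent on one mesh", {
  fx <- fix_injection_observed(E = 1200, D = 13, resolution = 3)
  f1 <- fit_injection(fx$observed, fx$geometry, fx$protocol,
                      init = c(E = 1800, D = 6.5), resolution = 3,
                      grid_n = 3)
  f2 <- fit_injection(fx$observed, fx$geometry, fx$protocol,
                      init = c(E = 1800, D = 6.5), resolution = 3,
                      grid_n = 3)
  # bitwise determinism of the derivative-free pipeline
  expect_identical(f1$E_Pa, f2$E_Pa)
  expect_identical(f1$D_um2_s, f2$D_um2_s)
  # observations came from the same mesh: near-exact recovery
  expect_equal(f1$E_Pa, 1200, tolerance = 0.01)
  expect_equal(f1$D_um2_s, 13, tolerance = 0.01)
  # stage-1 dominance: the refined optimum beats every grid point
  expect_lte(f1$objective, min(f1$grid$objective))
  # tidy/glance accessors
  td <- tidy(f1)
  expect_setequal(td$term, c("E_Pa", "D_um2_s"))
  expect_equal(glance(f1)$convergence, 0)
})

test_that("scaling observed displacements rescales E but not D (injection)", {
  fx <- fix_injection_observed(E = 1200, D = 13, resolution = 3)
  obs2 <- fx$observed
  obs2$u_z_um <- 2 * obs2$u_z_um
  f <- fit_injection(obs2, fx$geometry, fx$protocol,
                     init = c(E = 900, D = 10), resolution = 3, grid_n = 3)
  # twice the displacement at fixed P_eff means half the stiffness
  expect_equal(f$E_Pa, 600, tolerance = 0.05)
  expect_equal(f$D_um2_s, 13, tolerance = 0.10)
})

test_that("doubling the assumed P_eff doubles fitted E (documented covariance)", {
  fx <- fix_injection_observed(E = 1200, D = 13, P_eff = 500, resolution = 3)
  prot2 <- pressure_protocol(P_in = 0, P_app = 1000, ramp_time = 2,
                             duration = 8)
  f <- fit_injection(fx$observed, fx$geometry, prot2,
                     init = c(E = 2000, D = 10), resolution = 3, grid_n = 3)
  expect_equal(f$E_Pa, 2400, tolerance = 0.05)
})

test_that("recovery stays within 10% median bias under 5% noise", {
  fx <- fix_injection_observed(E = 1200, D = 13, resolution = 3)
  res <- lapply(1:5, function(s) {
    obs <- fx$observed
    set.seed(s)
    obs$u_z_um <- obs$u_z_um * exp(rnorm(nrow(obs), sd = 0.05))
    obs$dt_s <- obs$dt_s * exp(rnorm(nrow(obs), sd = 0.05))
    fit_injection(obs, fx$geometry, fx$protocol,
                  init = c(E = 1500, D = 9), resolution = 3, grid_n = 3)
  })
  Es <- vapply(res, function(f) f$E_Pa, numeric(1))
  Ds <- vapply(res, function(f) f$D_um2_s, numeric(1))
  expect_lt(abs(median(Es) / 1200 - 1), 0.10)
  expect_lt(abs(median(Ds) / 13 - 1), 0.10)
})
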