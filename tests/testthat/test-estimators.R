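test_that("time lag finds threshold crossings by interpolation", {
  # near-step trace: crossing pinned to the step time
  tt <- seq(0, 3, by = 0.001)
  step <- tibble::tibble(t_s = tt, z_um = ifelse(tt < 1.2, 0, 0.5))
  expect_equal(time_lag(step, rule = "absolute", threshold = 0.1), 1.2,
               tolerance = 0.002)
  # linear ramp 0.05 um/s crosses 0.1 um at exactly 2 s
  ramp <- tibble::tibble(t_s = 0:10, z_um = 0.05 * (0:10))
  expect_equal(time_lag(ramp, rule = "absolute", threshold = 0.1), 2.0)
  # fraction rule: 10% of the steady state
  sat <- tibble::tibble(t_s = seq(0, 10, 0.01),
                        z_um = 0.8 * (1 - exp(-seq(0, 10, 0.01) / 1.5)))
  dt <- time_lag(sat, rule = "fraction", threshold = 0.10)
  z_end <- 0.8 * (1 - exp(-10 / 1.5))
  expect_equal(0.8 * (1 - exp(-dt / 1.5)), 0.1 * z_end, tolerance = 1e-3)
  # a trace that never crosses yields NA, distinct from zero
  flat <- tibble::tibble(t_s = 0:10, z_um = rep(0.01, 11))
  expect_true(is.na(time_lag(flat, rule = "absolute", threshold = 0.1)))
  # downward traces are handled symmetrically under the fraction rule
  expect_equal(time_lag(dplyr::mutate(sat, z_um = -z_um), rule = "fraction"),
               dt)
})

test_that("time lag (fraction rule) is invariant to positive scaling", {
  tr <- gen_injection_traces(distances = 7, seed = 42, sigma_nm = 0)
  base <- time_lag(tr, rule = "fraction")
  for (c in c(0.2, 3, 50)) {
    scaled <- dplyr::mutate(tr, z_um = c * z_um)
    expect_equal(time_lag(scaled, rule = "fraction"), base)
  }
})

test_that("Monte-Carlo time lags on noisy sigmoids are unbiased", {
  lags <- vapply(1:100, function(s) {
    tr <- gen_injection_traces(distances = 8, seed = s, velocity_um_s = 10,
                               sigma_nm = 5)
    time_lag(tr, rule = "fraction", threshold = 0.10)
  }, numeric(1))
  # front arrives at 0.8 s; the saturating rise (tau = 0.5 s) crosses 10%
  # of steady state -0.5*log(0.9) s later, so the true 10% crossing is at
  t10 <- 0.8 - 0.5 * log(0.9)
  expect_lt(abs(median(lags) - t10), 0.05)
  expect_lt(sd(lags), 0.05)
})

test_that("darcy_fit recovers exact synthetic permeability and its units", {
  d <- gen_darcy_dataset(k = 0.125, dP = rep(c(300, 500, 800), 4),
                         dx = rep(c(4, 8, 12, 16), 3), seed = 1, noise = 0)
  fit <- darcy_fit(d)
  expect_equal(fit$k_um2_Pa_s, 0.125, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # unit bridge to SI
  expect_equal(k_um2_to_si(fit$k_um2_Pa_s), 1.25e-13)
  # records with non-positive lags are rejected and counted
  d2 <- d
  d2$dt_s[1] <- -1
  fit2 <- darcy_fit(d2)
  expect_equal(fit2$n_rejected, 1)
  expect_equal(fit2$n_used, nrow(d) - 1)
})

test_that("darcy_fit median recovery within 20% at 20% noise (200 seeds)", {
  ks <- vapply(1:200, function(s) {
    d <- gen_darcy_dataset(k = 0.05, dP = rep(c(300, 500, 800, 1200), 3),
                           dx = rep(c(5, 10, 15), 4), seed = s, noise = 0.2)
    darcy_fit(d)$k_um2_Pa_s
  }, numeric(1))
  expect_lt(abs(median(ks) / 0.05 - 1), 0.2)
})

test_that("darcy_fit is scale-equivariant in the pressure steps", {
  d <- gen_darcy_dataset(k = 0.08, dP = rep(c(200, 400, 600), 3),
                         dx = rep(c(5, 9, 13), 3), seed = 7, noise = 0.1)
  base <- darcy_fit(d)
  # scaling all pressures by c at fixed lags scales v-not, g by c: slope / c
  d2 <- dplyr::mutate(d, dP_Pa = 3 * dP_Pa)
  expect_equal(darcy_fit(d2)$k_um2_Pa_s, base$k_um2_Pa_s / 3,
               tolerance = 1e-12)
  expect_equal(darcy_fit(d2)$n_used, base$n_used)
})

test_that("hyperbolic lag fit recovers c and flags misfits", {
  d <- tibble::tibble(dP_Pa = c(100, 200, 400, 800),
                      dt_s = 200 / c(100, 200, 400, 800))
  fit <- hyperbolic_lag_fit(d)
  expect_equal(fit$c_Pa_s, 200, tolerance = 1e-12)
  expect_lt(fit$rel_rmse, 1e-12)
  # constant lags cannot be hyperbolic: large relative residual, no silent
  # success
  dbad <- tibble::tibble(dP_Pa = c(100, 200, 400, 800), dt_s = rep(1, 4))
  expect_gt(hyperbolic_lag_fit(dbad)$rel_rmse, 0.3)
  expect_error(hyperbolic_lag_fit(tibble::tibble(dP_Pa = c(-1, 2, 3),
                                                 dt_s = 1:3)), "positive")
  expect_error(hyperbolic_lag_fit(tibble::tibble(dP_Pa = c(100, 100, 100),
                                                 dt_s = 1:3)), "distinct")
})

test_that("hyperbolic fit recovers c within 15% at 10% noise", {
  # through the full diameter pipeline the onset threshold (0.02 um at a
  # rate r0 * dP) adds exactly thr/r0 to the hyperbolic constant, so the
  # pipeline's own truth is c + 0.02/1e-3 = c + 20
  cs <- vapply(1:200, function(s) {
    series <- gen_metaphase_diameter(dP = c(100, 200, 400), seed = s,
                                     c_Pa_s = 150, noise = 0.1,
                                     sigma_um = 0.002)
    lags <- diameter_onset_lags(series, threshold_um = 0.02)
    hyperbolic_lag_fit(dplyr::filter(lags, is.finite(dt_s)))$c_Pa_s
  }, numeric(1))
  expect_lt(abs(median(cs) / 170 - 1), 0.15)
})

test_that("tau_p fit is exact on a pure exponential", {
  tt <- seq(0, 8, by = 0.02)
  tr <- tibble::tibble(t_s = tt, z_um = 0.5 - 0.3 * exp(-tt / 2))
  fit <- tau_p_fit(tr, phase_split_time = 0.3)
  expect_equal(fit$tau_p_s, 2, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("tau_p recovery is unbiased on noisy biphasic traces (100 seeds)", {
  taus <- vapply(1:100, function(s) {
    tr <- gen_biphasic_traces(distances = 5, seed = s,
                              tau_p = function(r) 1.5, sigma_nm = 5)
    tau_p_fit(tr, phase_split_time = 0.3)$tau_p_s
  }, numeric(1))
  expect_lt(abs(median(taus) / 1.5 - 1), 0.05)
  expect_lt(abs(mean(taus) / 1.5 - 1), 0.05)
})

test_that("a 3.5-fold tau_p change is resolved within 10%", {
  # paired traces emulating the osmotic-compression effect size
  r1 <- vapply(1:40, function(s) {
    tr <- gen_biphasic_traces(distances = 6.5, seed = s,
                              tau_p = function(r) 1, sigma_nm = 5)
    tau_p_fit(tr)$tau_p_s
  }, numeric(1))
  r2 <- vapply(1:40, function(s) {
    tr <- gen_biphasic_traces(distances = 6.5, seed = 1000 + s,
                              tau_p = function(r) 3.5, t_end = 16,
                              sigma_nm = 5)
    tau_p_fit(tr)$tau_p_s
  }, numeric(1))
  expect_equal(median(r2) / median(r1), 3.5, tolerance = 0.1)
})
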