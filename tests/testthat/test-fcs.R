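test_that("autocorrelation estimator handles canonical traces", {
  # constant trace: no fluctuations, G identically 0
  g <- autocorrelate(rep(5, 4000), dt_s = 1e-5)
  expect_true(all(abs(g$curve$G) < 1e-12))
  # perfectly anticorrelated alternating trace: G(dt) = -1
  alt <- rep(c(0, 2), 2000)
  ga <- autocorrelate(alt, dt_s = 1e-5)
  expect_equal(ga$curve$G[1], -1, tolerance = 1e-9)
  expect_error(autocorrelate(rep(0, 4000), dt_s = 1e-5), "zero-mean")
  expect_error(autocorrelate(1:10, dt_s = 1e-5), "too short")
  # lag grid is strictly increasing and quasi-logarithmic
  expect_true(all(diff(ga$curve$lag_s) > 0))
})

test_that("3D diffusion model algebra: G(0) = 1/N, strict decay, limits", {
  N <- 30; tauD <- 1e-3; kappa <- 5.6
  expect_equal(fcs_model_3d(0, N, tauD, kappa), 1 / N)
  tau <- 10^seq(-6, 1, by = 0.1)
  g <- fcs_model_3d(tau, N, tauD, kappa)
  expect_true(all(diff(g) < 0))
  expect_lt(g[length(g)], 1e-3 / N)
  expect_equal(fcs_model_3d(1e-9, N, tauD, kappa), 1 / N,
               tolerance = 1e-5)
})

test_that("fit recovers parameters from a noiseless model curve", {
  lag <- 10^seq(-5.5, -0.5, length.out = 60)
  curve <- data.frame(lag_s = lag,
                      G = fcs_model_3d(lag, 30, 1e-3, 5.6),
                      n_pairs = rep(1, 60))
  fit <- fit_fcs(curve, fix_kappa = 5.6)
  expect_equal(fit$N, 30, tolerance = 1e-6)
  expect_equal(fit$tau_D_s, 1e-3, tolerance = 1e-6)
  fit2 <- fit_fcs(curve)
  expect_equal(fit2$kappa, 5.6, tolerance = 1e-3)
  expect_error(fit_fcs(curve[1:5, ]), "at least 10")
})

test_that("calibration follows the confocal volume formulas", {
  cal <- calibrate(list(tau_D_s = 61.03e-6, kappa = 5.6),
                   D_ref_um2s = 400)
  expect_equal(cal$w0_um, sqrt(4 * 400 * 61.03e-6))
  expect_equal(cal$z0_um, 5.6 * cal$w0_um)
  expect_equal(cal$V_eff_fl, pi^1.5 * cal$w0_um^2 * cal$z0_um)
  # direct evaluation: w0 = 0.25 um, kappa = 5.6 -> ~0.487 fl
  cal2 <- calibrate(list(tau_D_s = 0.25^2 / (4 * 400), kappa = 5.6),
                    D_ref_um2s = 400)
  expect_equal(cal2$w0_um, 0.25, tolerance = 1e-12)
  expect_equal(cal2$V_eff_fl, pi^1.5 * 0.25^2 * 1.4, tolerance = 1e-12)
  expect_equal(round(cal2$V_eff_fl, 3), 0.487)
  # doubling D at fixed tau_D doubles w0^2 and scales V_eff by 2^1.5
  cal3 <- calibrate(list(tau_D_s = 61.03e-6, kappa = 5.6),
                    D_ref_um2s = 800)
  expect_equal(cal3$w0_um^2, 2 * cal$w0_um^2)
  expect_equal(cal3$V_eff_fl, 2^1.5 * cal$V_eff_fl)
  # z0 = kappa * w0 dimensional consistency
  expect_equal(cal$z0_um / cal$w0_um, cal$kappa)
})

test_that("concentration conversion is exact and linear", {
  # N = 30.3 in 0.95 fl is about 53 nM
  expect_equal(concentration(30.3, 0.95) * 1e9, 53, tolerance = 0.01)
  # definitional check: N = 1 in 1/(N_A * 1e-9 L) fl is exactly 1 nM
  V <- 1 / (6.02214076e23 * 1e-9) / 1e-15
  expect_equal(concentration(1, V), 1e-9)
  expect_equal(concentration(60.6, 0.95), 2 * concentration(30.3, 0.95))
  expect_error(concentration(-1, 1))
})

test_that("FCS curve/calibration exports round trip through CSV/JSON", {
  lag <- 10^seq(-5, -1, length.out = 30)
  curve <- structure(list(curve = data.frame(
    lag_s = lag, G = fcs_model_3d(lag, 20, 1e-3, 5.6),
    n_pairs = rep(100, 30)), dt_s = 1e-5, duration_s = 1),
    class = "fcs_curve")
  fit <- fit_fcs(curve, fix_kappa = 5.6)
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- write_fcs_curve(curve, path, fit)
  back <- utils::read.csv(path)
  expect_equal(back$G, curve$curve$G)
  expect_equal(back$G_fit, back$G, tolerance = 1e-6)
  cal <- calibrate(fit, 400)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cal, jpath)
  got <- jsonlite::fromJSON(jpath)
  expect_equal(got$V_eff_fl, cal$V_eff_fl)
  expect_equal(got$kappa, 5.6)
})

test_that("brownian simulator obeys its contracts", {
  # zero brightness -> pure background trace
  tr <- simulate_fcs_photons(5e-8, 400, 0.31, 5.6, brightness_cps = 0,
                             background_cps = 2e4, duration_s = 0.05,
                             dt_s = 5e-6, seed = 3L)
  expect_equal(length(tr$counts), 1e4)
  expect_equal(mean(tr$counts) / tr$dt_s, 2e4, tolerance = 0.05)
  # same seed, identical trace; different seed, different trace
  a <- simulate_fcs_photons(2e-8, 400, 0.31, 5.6, 5e4, 0, 0.02, 5e-6, 11L)
  b <- simulate_fcs_photons(2e-8, 400, 0.31, 5.6, 5e4, 0, 0.02, 5e-6, 11L)
  c <- simulate_fcs_photons(2e-8, 400, 0.31, 5.6, 5e4, 0, 0.02, 5e-6, 12L)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, c$counts))
  # step-size guard
  expect_error(simulate_fcs_photons(2e-8, 400, 0.31, 5.6, 5e4, 0, 1,
                                    1e-4, 1L), "dt too coarse")
  expect_error(simulate_fcs_photons(2e-8, 400, 0.31, 5.6, 5e4, 0, 1,
                                    5e-6, 1L, box_factor = 4), "box_factor")
})

test_that("ziggurat normals have standard-normal moments and tails", {
  z <- sflimfret:::.ziggurat_normals(4e5, 123L)
  expect_lt(abs(mean(z)), 4 / sqrt(4e5))
  expect_lt(abs(var(z) - 1), 0.02)
  expect_lt(abs(mean(z^3)), 0.03)
  expect_lt(abs(mean(z > 2) - pnorm(-2)), 0.003)
  expect_lt(abs(mean(z < -2) - pnorm(-2)), 0.003)
})

test_that("simulated mean count rate matches the detection-integral expectation", {
  w0 <- 0.31; kappa <- 5.6; B <- 5e4; C <- 3e-8
  tr <- simulate_fcs_photons(C, 400, w0, kappa, B, 0, duration_s = 0.4,
                             dt_s = 5e-6, seed = 21L)
  # analytic mean: n_mol * B * integral(MDF) / V_box with
  # integral(MDF) = (pi/2)^(3/2) w0^3 kappa
  n_mol <- tr$params$n_molecules
  V_box_um3 <- tr$params$V_box_L / 1e-15
  expected <- n_mol * B * (pi / 2)^1.5 * w0^3 * kappa / V_box_um3
  got <- mean(tr$counts) / tr$dt_s
  expect_lt(abs(got - expected) / expected, 0.15)
})

test_that("short-trace FCS round trip lands near the simulated concentration", {
  # a fast, loose version of the full recovery: high concentration and a
  # short trace keep the runtime small, at the cost of wider scatter
  w0 <- 0.31; kappa <- 5.6
  C <- 2e-7
  tr <- simulate_fcs_photons(C, 400, w0, kappa, brightness_cps = 6e4,
                             background_cps = 0, duration_s = 3,
                             dt_s = 7e-6, seed = 17L)
  ac <- autocorrelate(tr, max_lag_s = 0.02)
  fit <- fit_fcs(ac, fix_kappa = kappa)
  V_eff <- pi^1.5 * w0^3 * kappa
  C_hat <- concentration(fit$N, V_eff)
  expect_lt(abs(C_hat - C) / C, 0.25)
})
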