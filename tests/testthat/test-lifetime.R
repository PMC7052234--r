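test_that("weighted mean lifetimes follow the standard definitions", {
  s <- lifetime_summary(data.frame(amplitude = 1, tau_ns = 4))
  expect_equal(s$tau_int, 4)
  expect_equal(s$tau_amp, 4)
  s2 <- lifetime_summary(data.frame(amplitude = c(0.5, 0.5),
                                    tau_ns = c(4, 1)))
  expect_equal(s2$tau_int, 3.4)
  expect_equal(s2$tau_amp, 2.5)
  # homogeneity: scaling amplitudes leaves both unchanged
  s3 <- lifetime_summary(data.frame(amplitude = c(5, 5), tau_ns = c(4, 1)))
  expect_equal(s3$tau_int, s2$tau_int)
  expect_equal(s3$tau_amp, s2$tau_amp)
  expect_error(lifetime_summary(data.frame(amplitude = c(0, 0),
                                           tau_ns = c(1, 2))), "zero")
})

test_that("tau_amp <= tau_int for random component sets, equality iff mono", {
  withr::with_seed(42, {
    for (i in 1:50) {
      k <- sample(1:4, 1)
      comp <- data.frame(amplitude = stats::runif(k, 0.01, 1),
                         tau_ns = stats::runif(k, 0.1, 6))
      s <- lifetime_summary(comp)
      expect_lte(s$tau_amp, s$tau_int + 1e-12)
      expect_gte(s$tau_int, min(comp$tau_ns) - 1e-12)
      expect_lte(s$tau_int, max(comp$tau_ns) + 1e-12)
      if (k == 1L) expect_equal(s$tau_amp, s$tau_int)
    }
  })
})

test_that("reconvolved model: background, delta-IRF closed form, linearity", {
  cfg <- tiny_config(n_tcspc = 128L)
  irf <- delta_irf(cfg)
  nb <- bins_per_epoch(cfg)
  # background only -> flat vector
  flat <- reconvolved_model(data.frame(amplitude = 0, tau_ns = 1),
                            background = 2.5, irf = irf, epoch = 1L,
                            config = cfg)
  expect_equal(flat, rep(2.5, nb))
  # delta IRF, tau = 2 ns: periodic-sum-corrected exponential at centers
  m <- reconvolved_model(data.frame(amplitude = 3, tau_ns = 2),
                         irf = irf, epoch = 1L, config = cfg)
  t <- (seq_len(nb) - 0.5) * tcspc_bin_width_ns(cfg)
  closed <- 3 * exp(-t / 2) / (1 - exp(-sync_period_ns(cfg) / 2))
  expect_equal(m, closed, tolerance = 1e-9)
  # linearity in components
  c1 <- data.frame(amplitude = 2, tau_ns = 1.3)
  c2 <- data.frame(amplitude = 5, tau_ns = 3.1)
  m12 <- reconvolved_model(rbind(c1, c2), background = 1, irf = irf,
                           epoch = 1L, config = cfg)
  m1 <- reconvolved_model(c1, background = 1, irf = irf, epoch = 1L,
                          config = cfg)
  m2 <- reconvolved_model(c2, background = 1, irf = irf, epoch = 1L,
                          config = cfg)
  expect_equal(m12, m1 + m2 - 1, tolerance = 1e-10)
  expect_error(reconvolved_model(data.frame(amplitude = 1, tau_ns = -1),
                                 irf = irf, config = cfg), "positive")
})

test_that("gaussian IRF tends to the pure periodic exponential as width -> 0", {
  cfg <- tiny_config(n_tcspc = 256L)
  narrow <- gaussian_irf(cfg, fwhm_ps = 1e-4, delay_ns = 0)
  m <- reconvolved_model(data.frame(amplitude = 1, tau_ns = 2),
                         irf = narrow, epoch = 1L, config = cfg)
  t <- (seq_len(bins_per_epoch(cfg)) - 0.5) * tcspc_bin_width_ns(cfg)
  pure <- exp(-t / 2) / (1 - exp(-sync_period_ns(cfg) / 2))
  expect_lt(max(abs(m - pure)), 1e-6)
})

test_that("decay fit is self-consistent on noiseless curves", {
  cfg <- default_config()
  irf <- gaussian_irf(cfg)
  h <- simulate_decay_histogram(3.0, 1e6, irf, 1L, cfg, seed = NULL)
  fit <- fit_decay(h, irf, 1L, cfg, n_components = 1L)
  expect_lt(abs(fit$components$tau_ns - 3.0), 0.01)
  expect_lt(fit$chi2_red, 0.05)
})

test_that("decay fit recovers lifetimes from Poisson samples", {
  cfg <- default_config()
  irf <- gaussian_irf(cfg)
  # mono-exponential at the unquenched donor lifetime, 1e6 photons
  h <- simulate_decay_histogram(3.84, 1e6, irf, 1L, cfg,
                                background_fraction = 0.01, seed = 21L)
  fit <- fit_decay(h, irf, 1L, cfg)
  expect_lt(abs(fit$summary$tau_int - 3.84), 0.02)
  expect_lt(fit$chi2_red, 1.25)
  # two well-separated components recovered within 10%
  h2 <- simulate_decay_histogram(
    data.frame(fraction = c(0.7, 0.3), tau_ns = c(4.0, 0.5)),
    1e6, irf, 1L, cfg, background_fraction = 0.005, seed = 22L)
  fit2 <- fit_decay(h2, irf, 1L, cfg)
  expect_lt(abs(fit2$components$tau_ns[1] - 4.0) / 4.0, 0.10)
  expect_lt(abs(fit2$components$tau_ns[2] - 0.5) / 0.5, 0.10)
  # fit is deterministic for fixed data
  fit2b <- fit_decay(h2, irf, 1L, cfg)
  expect_identical(fit2$components, fit2b$components)
})

test_that("decay fit has low bias over replicates", {
  cfg <- sflim_config(n_tcspc = 512L)  # coarser grid keeps this cheap
  irf <- gaussian_irf(cfg)
  taus <- vapply(1:12, function(i) {
    h <- simulate_decay_histogram(2.5, 1e5, irf, 1L, cfg,
                                  background_fraction = 0.01,
                                  seed = 400L + i)
    fit_decay(h, irf, 1L, cfg)$summary$tau_int
  }, numeric(1))
  expect_lt(abs(mean(taus) - 2.5) / 2.5, 0.01)
})

test_that("low-signal histograms are refused with a clear error", {
  cfg <- tiny_config()
  irf <- gaussian_irf(cfg)
  h <- simulate_decay_histogram(3, 200, irf, 1L, cfg, seed = 5L)
  expect_error(fit_decay(h, irf, 1L, cfg), class = "sflim_low_signal_error")
})

test_that("FRET quantities follow the lifetime drop", {
  fq <- fret_quant(3.84, 3.18)
  expect_equal(fq$delta_tau_int, 0.66)
  expect_equal(fq$efficiency, 1 - 3.18 / 3.84)
  expect_equal(round(fq$efficiency, 3), 0.172)
  same <- fret_quant(3.5, 3.5)
  expect_equal(same$delta_tau_int, 0)
  expect_equal(same$efficiency, 0)
  expect_error(fret_quant(0, 1), "positive")
})

test_that("fit tables export one CSV row per component", {
  cfg <- sflim_config(n_tcspc = 512L)
  irf <- gaussian_irf(cfg)
  h <- simulate_decay_histogram(2.5, 5e4, irf, 1L, cfg, seed = 2L)
  fit <- fit_decay(h, irf, 1L, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- write_fit_table(list(sample_a = fit), path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$tau_ns, fit$components$tau_ns)
  expect_equal(back$tau_int_ns, rep(fit$summary$tau_int, 2L))
})

test_that("group comparison is a classical equal-variance t-test", {
  a <- c(3.83, 3.84, 3.85)
  b <- c(3.17, 3.18, 3.19)
  r <- compare_lifetimes(a, b)
  expect_lt(r$p, 0.001)
  # matches stats::t.test with var.equal = TRUE
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  expect_equal(r$df, unname(ref$parameter))
  # identical groups -> p = 1 by the zero-variance convention
  expect_equal(compare_lifetimes(c(3, 3), c(3, 3))$p, 1)
  expect_equal(compare_lifetimes(c(3, 3), c(4, 4))$p, 0)
  # antisymmetry
  expect_equal(compare_lifetimes(a, b)$t, -compare_lifetimes(b, a)$t)
  expect_error(compare_lifetimes(1, c(1, 2)), "at least 2")
})
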