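test_that("structure maps are deterministic, bounded and kind-checked", {
  z <- structure_map("puncta", c(64, 64), list(count = 0L), seed = 1L)
  expect_equal(sum(z), 0)
  for (kind in c("puncta", "filaments", "blobs")) {
    a <- structure_map(kind, c(48, 48), list(count = 5L), seed = 11L)
    b <- structure_map(kind, c(48, 48), list(count = 5L), seed = 11L)
    expect_identical(a, b)
    expect_true(min(a) >= 0 && max(a) <= 1)
  }
  expect_error(structure_map("voronoi", c(8, 8), list(count = 1L), 1L),
               "unknown structure kind")
})

test_that("filament maps are connected curvilinear supports", {
  m <- structure_map("filaments", c(128, 128), list(count = 5L), seed = 3L)
  nz <- which(m > 0, arr.ind = TRUE)
  expect_gt(nrow(nz), 100)
  # >= 95% of nonzero pixels have a nonzero 8-neighbour
  has_neighbour <- vapply(seq_len(nrow(nz)), function(i) {
    r <- nz[i, 1]; c <- nz[i, 2]
    rs <- max(1, r - 1):min(128, r + 1)
    cs <- max(1, c - 1):min(128, c + 1)
    sum(m[rs, cs] > 0) > 1
  }, logical(1))
  expect_gte(mean(has_neighbour), 0.95)
})

test_that("emission channel probabilities integrate the spectrum", {
  cfg <- default_config()
  fl <- fluorophore("f520", 520, 15, decay = 3, excitation = c(1, 0))
  p <- emission_channel_probs(fl, cfg)
  expect_prob_vector(p)
  # argmax in the channel covering 508.75-527.5 nm
  expect_equal(which.max(p), 2L)
  expect_equal(spectral_channel_of(520, cfg), 2L)
  # notch attenuates only the 561 nm channel (index 4)
  cfg_no_notch <- sflim_config(notch = NULL)
  p0 <- emission_channel_probs(fl, cfg_no_notch)
  raw <- p0
  att <- raw
  att[4] <- att[4] * 0.2
  expect_equal(p, att / sum(att), tolerance = 1e-12)
  # narrow spectrum limit: all mass in the containing channel
  sharp <- fluorophore("sharp", 520, 1e-3, decay = 3, excitation = c(1, 0))
  ps <- emission_channel_probs(sharp, cfg)
  expect_equal(ps[2], 1, tolerance = 1e-9)
  # no overlap with the detection range -> error
  uv <- fluorophore("uv", 350, 5, decay = 3, excitation = c(1, 0))
  expect_error(emission_channel_probs(uv, cfg), "overlap")
})

test_that("FRET quenching scales lifetimes and brightness by 1 - E", {
  d <- tiny_donor()
  expect_equal(fret_modified_donor(d, 0)$decay$tau_ns, d$decay$tau_ns)
  q <- fret_modified_donor(d, 0.171875)
  expect_equal(q$decay$tau_ns, 3.18)
  expect_equal(q$brightness, d$brightness * (1 - 0.171875))
  expect_equal(q$decay$fraction, d$decay$fraction)
  # E -> 1 limit: lifetimes and brightness vanish
  q99 <- fret_modified_donor(d, 1 - 1e-9)
  expect_lt(max(q99$decay$tau_ns), 1e-8)
  expect_lt(q99$brightness, 1e-8)
  expect_error(fret_modified_donor(d, 1), "efficiency")
  expect_error(fret_modified_donor(d, -0.1), "efficiency")
})

test_that("sensitized decay shape has unit mass and a delayed peak", {
  cfg <- tiny_config(n_tcspc = 512L)
  irf <- delta_irf(cfg)
  s1 <- sensitized_decay_shape(1.0, 4.0, 1, cfg, irf)
  expect_prob_vector(s1)
  # closed-form peak position t* = ln(tauA/tauDA) / (1/tauDA - 1/tauA)
  tstar <- log(4 / 1) / (1 / 1 - 1 / 4)
  dt <- tcspc_bin_width_ns(cfg)
  expect_lt(abs((which.max(s1) - 0.5) * dt - tstar), 3 * dt)
  # later rise for slower feeding
  s2 <- sensitized_decay_shape(2.0, 4.0, 1, cfg, irf)
  expect_gt(which.max(s2), which.max(s1))
  # fast-transfer limit approaches the pure acceptor decay
  s0 <- sensitized_decay_shape(1e-3, 4.0, 1, cfg, irf)
  pure <- decay_shape(4.0, 1, cfg, irf)
  expect_lt(max(abs(s0 - pure)), 5e-3)
  expect_error(sensitized_decay_shape(2, 2, 1, cfg, irf), "limit form")
})

test_that("ground-truth patterns carry the FRET fingerprint", {
  cfg <- default_config()
  irf <- gaussian_irf(cfg)
  donor <- tiny_donor()
  p_d <- ground_truth_pattern(donor, cfg, irf)
  expect_prob_vector(as.numeric(p_d$p))
  # donor excited almost exclusively by laser 1: epoch-2 mass is only the
  # periodic wrap of the decay plus the tiny 561 nm excitation
  epoch_mass <- apply(p_d$p, 1, sum)
  expect_gt(epoch_mass[1], 0.85)
  # a pure single-laser donor concentrates all mass in epoch 1 up to wrap
  mono <- fluorophore("mono", 519, 14, decay = 0.5, excitation = c(1, 0))
  pm <- ground_truth_pattern(mono, cfg, irf)
  expect_gt(sum(pm$p[1, , ]), 0.999)
  # FRET pair: acceptor-band mass in the donor epoch exceeds donor-only
  pair <- tiny_pair()
  p_f <- ground_truth_pattern(pair, cfg, irf)
  acc_ch <- spectral_channel_of(573, cfg)
  expect_gt(sum(p_f$p[1, acc_ch:8, ]), 10 * sum(p_d$p[1, acc_ch:8, ]))
})

test_that("FRET monotonicity: more transfer, shorter donor, more sensitized mass", {
  cfg <- tiny_config(n_tcspc = 256L)
  irf <- gaussian_irf(cfg)
  acc_ch <- spectral_channel_of(573, cfg)
  taus <- c(); masses <- c()
  for (E in c(0.05, 0.2, 0.4, 0.6)) {
    pair <- tiny_pair(E = E)
    q <- fret_modified_donor(pair$donor, E)
    taus <- c(taus, lifetime_summary(
      data.frame(amplitude = q$decay$fraction, tau_ns = q$decay$tau_ns))$tau_int)
    pf <- ground_truth_pattern(pair, cfg, irf)
    masses <- c(masses, sum(pf$p[1, acc_ch:cfg$n_spectral, ]))
  }
  expect_true(all(diff(taus) < 0))
  expect_true(all(diff(masses) > 0))
})

test_that("simulated cubes match their forward model", {
  cfg <- tiny_config()
  irf <- gaussian_irf(cfg)
  scene <- tiny_scene(background = 0.01)
  # zero exposure -> empty cube
  z <- simulate_cube(scene, cfg, irf, exposure = 0, seed = 1L)
  expect_equal(sum(z$cube$counts), 0)
  expect_error(simulate_cube(scene, cfg, irf, exposure = -1),
               "nonnegative")
  # determinism
  a <- simulate_cube(scene, cfg, irf, exposure = 20, seed = 9L)
  b <- simulate_cube(scene, cfg, irf, exposure = 20, seed = 9L)
  expect_identical(a$cube$counts, b$cube$counts)
  # expected contribution maps follow density * brightness * exposure
  expect_equal(a$truth$expected[[1]],
               a$truth$density[[1]] *
                 label_brightness(scene$structures[[1]]$label, cfg) * 20)
})

test_that("per-pixel counts are Poisson around the pattern-weighted mean", {
  cfg <- tiny_config(n_tcspc = 32L, n_spectral = 2L)
  irf <- gaussian_irf(cfg)
  one_px <- scene_spec(shape = c(1L, 1L),
                       structures = list(list(
                         kind = "blobs",
                         params = list(count = 12L, ax = 4, ay = 4),
                         label = tiny_donor())),
                       background = 0, seed = 2L)
  lambda_tot <- label_brightness(tiny_donor(), cfg) * 40 *
    scene_densities(one_px)[[1]][1, 1]
  expect_gt(lambda_tot, 5)
  p <- as.numeric(ground_truth_pattern(tiny_donor(), cfg,
                                       irf)$p)
  reps <- 200L
  counts <- vapply(seq_len(reps), function(i)
    as.numeric(simulate_cube(one_px, cfg, irf, exposure = 40,
                             seed = 1000L + i)$cube$counts),
    numeric(length(p)))
  mu_hat <- rowMeans(counts)
  mu <- lambda_tot * p
  # mean within 3 standard errors, checked on the well-populated bins
  big <- mu > 0.2
  se <- sqrt(mu[big] / reps)
  expect_true(all(abs(mu_hat[big] - mu[big]) < 3.5 * se + 1e-9))
  # index of dispersion of the per-replicate totals near 1
  totals <- colSums(counts)
  expect_gt(var(totals) / mean(totals), 0.75)
  expect_lt(var(totals) / mean(totals), 1.3)
})
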