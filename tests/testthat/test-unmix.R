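test_that("pattern extraction returns the exact pattern for scaled pixels", {
  cfg <- tiny_config()
  p <- ground_truth_pattern(tiny_donor(), cfg, gaussian_irf(cfg))
  counts <- array(0L, dim = c(2, 2, dim(p$p)))
  counts[1, 1, , , ] <- round(2e5 * p$p)
  cube <- sflim_cube(counts, cfg)
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  got <- extract_pattern(cube, mask, "donor")
  expect_equal(got$p, round(2e5 * p$p) / sum(round(2e5 * p$p)),
               tolerance = 1e-12)
  expect_equal(got$meta$n_pixels, 1L)
  expect_error(extract_pattern(cube, matrix(FALSE, 2, 2), "x"),
               "empty")
  expect_error(extract_pattern(cube, mask, "x", min_counts = 1e9),
               class = "sflim_low_signal_error")
})

test_that("patterns from disjoint masks of one species agree closely", {
  cfg <- tiny_config()
  irf <- gaussian_irf(cfg)
  scene <- scene_spec(shape = c(24L, 24L),
                      structures = list(list(
                        kind = "blobs", params = list(count = 40L, ax = 6, ay = 6),
                        label = tiny_donor())),
                      background = 0, seed = 4L)
  sim <- simulate_cube(scene, cfg, irf, exposure = 600, seed = 8L)
  half1 <- matrix(FALSE, 24, 24); half1[, 1:12] <- TRUE
  half2 <- !half1
  p1 <- extract_pattern(sim$cube, half1, "a")
  p2 <- extract_pattern(sim$cube, half2, "b")
  expect_gte(p1$meta$merged_counts, 1e5)
  tv <- 0.5 * sum(abs(p1$p - p2$p))
  expect_lt(tv, 0.02)
})

test_that("pixel unmixing handles pure, empty and degenerate inputs", {
  p1 <- c(0.5, 0.3, 0.1, 0.05, 0.03, 0.02)
  p2 <- rev(p1)
  f <- unmix_pixel(1000 * p1, list(p1, p2), tol = 1e-12,
                   max_iter = 20000L, accelerate = TRUE)
  expect_equal(f[[1]], 1000, tolerance = 1e-6)
  expect_lt(f[[2]] / 1000, 1e-6)  # zero up to solver resolution
  expect_equal(as.numeric(unmix_pixel(rep(0, 6), list(p1, p2))), c(0, 0))
  # a pattern with zero mass on all observed bins gets zero contribution
  p3 <- c(0, 0, 0, 0, 0.5, 0.5)
  n <- c(40, 30, 20, 10, 0, 0)
  f3 <- unmix_pixel(n, list(p1 / sum(p1), p3))
  expect_equal(as.numeric(f3[2]), 0)
  expect_equal(sum(f3), sum(n), tolerance = 1e-6)
})

test_that("EM matches a dense simplex grid search on random 2-pattern problems", {
  withr::with_seed(12, {
    for (i in 1:60) {
      p1 <- stats::runif(6); p1 <- p1 / sum(p1)
      p2 <- stats::runif(6); p2 <- p2 / sum(p2)
      th_true <- stats::runif(1)
      n <- stats::rpois(6, 800 * (th_true * p1 + (1 - th_true) * p2))
      if (sum(n) == 0) next
      f <- unmix_pixel(n, list(p1, p2), tol = 1e-12, max_iter = 5000L)
      tot <- sum(n)
      # brute-force oracle over the scaled 2-simplex
      th <- seq(0, 1, by = 1e-3)
      ll <- vapply(th, function(t) {
        mu <- pmax(tot * (t * p1 + (1 - t) * p2), 1e-300)
        sum(n * log(mu)) - sum(mu)
      }, numeric(1))
      th_star <- th[which.max(ll)]
      expect_lt(abs(f[1] / tot - th_star), 2e-3)
      expect_equal(sum(f), tot, tolerance = 1e-6)
    }
  })
})

test_that("EM log-likelihood is monotone along the iteration path", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      K <- 8L
      P <- t(vapply(1:3, function(j) {
        v <- stats::runif(K); v / sum(v)
      }, numeric(K)))
      n <- stats::rpois(K, 50 * stats::runif(K))
      f <- rep(sum(n) / 3, 3)
      ll_path <- numeric(30)
      for (it in 1:30) {
        mu <- pmax(as.numeric(f %*% P), 1e-300)
        ll_path[it] <- sum(n * log(mu)) - sum(mu)
        f <- f * as.numeric(P %*% (n / mu))
      }
      expect_true(all(diff(ll_path) > -1e-9))
    }
  })
})

test_that("unmixing is permutation- and scale-equivariant", {
  p1 <- c(0.6, 0.2, 0.1, 0.1); p2 <- c(0.1, 0.1, 0.2, 0.6)
  n <- c(300, 120, 90, 250)
  f12 <- unmix_pixel(n, list(p1, p2), tol = 1e-12, max_iter = 5000L)
  f21 <- unmix_pixel(n, list(p2, p1), tol = 1e-12, max_iter = 5000L)
  expect_equal(as.numeric(f12), rev(as.numeric(f21)), tolerance = 1e-6)
  # integer-scaled noiseless input scales contributions
  mix <- 400 * p1 + 100 * p2
  fa <- unmix_pixel(mix, list(p1, p2), tol = 1e-13, max_iter = 20000L)
  fb <- unmix_pixel(3 * mix, list(p1, p2), tol = 1e-13, max_iter = 20000L)
  expect_equal(as.numeric(fb), 3 * as.numeric(fa), tolerance = 1e-4)
})

test_that("cube unmixing conserves counts and separates a pure scene", {
  cfg <- tiny_config()
  irf <- gaussian_irf(cfg)
  scene <- tiny_scene(label = tiny_donor(), background = 0)
  sim <- simulate_cube(scene, cfg, irf, exposure = 400, seed = 13L)
  pats <- list(ground_truth_pattern(tiny_donor(), cfg, irf),
               ground_truth_pattern(tiny_acceptor(), cfg, irf))
  um <- unmix_cube(sim$cube, pats, background = FALSE, rebin = 2L)
  tot_pix <- cube_intensity(sim$cube)
  recon <- um$contributions[[1]] + um$contributions[[2]]
  expect_lt(max(abs(recon - tot_pix) / pmax(tot_pix, 1)), 1e-6)
  # second pattern picks up almost nothing
  frac2 <- sum(um$contributions[[2]]) / sum(tot_pix)
  expect_lt(frac2, 0.01)
  expect_true(um$converged)
})

test_that("mixed pixels are recovered at the true fractions on average", {
  cfg <- tiny_config()
  irf <- gaussian_irf(cfg)
  pd <- ground_truth_pattern(tiny_donor(), cfg, irf)
  pa <- ground_truth_pattern(tiny_acceptor(), cfg, irf)
  vd <- as.numeric(pd$p); va <- as.numeric(pa$p)
  mu <- 1e4 * (0.7 * vd + 0.3 * va)
  fr <- withr::with_seed(31, t(vapply(1:60, function(i) {
    n <- stats::rpois(length(mu), mu)
    f <- unmix_pixel(n, list(vd, va), tol = 1e-10, max_iter = 2000L)
    f / sum(f)
  }, numeric(2))))
  expect_lt(abs(mean(fr[, 1]) - 0.7), 0.02)
  expect_lt(abs(mean(fr[, 2]) - 0.3), 0.02)
})

test_that("unmixing refuses patterns from a different configuration", {
  cfg <- tiny_config()
  other <- tiny_config(n_tcspc = 128L)
  irf <- gaussian_irf(cfg)
  sim <- simulate_cube(tiny_scene(), cfg, irf, exposure = 50, seed = 2L)
  pat_other <- ground_truth_pattern(tiny_donor(), other)
  expect_error(unmix_cube(sim$cube, list(pat_other)),
               class = "sflim_hash_error")
})

test_that("bleed-through matrix is the identity for noiseless pure regions", {
  cfg <- tiny_config()
  irf <- gaussian_irf(cfg)
  pd <- ground_truth_pattern(tiny_donor(), cfg, irf)
  pa <- ground_truth_pattern(tiny_acceptor(), cfg, irf)
  d <- c(2, 2, dim(pd$p))
  counts <- array(0L, dim = d)
  counts[1, 1, , , ] <- round(5e4 * pd$p)
  counts[2, 2, , , ] <- round(5e4 * pa$p)
  cube <- sflim_cube(counts, cfg)
  um <- unmix_cube(cube, list(pd, pa), background = FALSE, rebin = 1L,
                   tol = 1e-12, max_iter = 2000L)
  m1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  m2 <- matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2)
  B <- bleedthrough(um, list(donor = m1, acceptor = m2))
  expect_equal(rowSums(B), c(donor = 1, acceptor = 1), tolerance = 1e-12)
  expect_gt(B[1, 1], 0.995)
  expect_gt(B[2, 2], 0.995)
  expect_error(bleedthrough(um, list(matrix(FALSE, 2, 2))), "empty")
  expect_error(bleedthrough(um, list(a = m1, b = m1)), "disjoint")
})
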