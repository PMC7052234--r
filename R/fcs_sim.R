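#' Simulate FCS photon traces by Brownian dynamics
#'
#' Point emitters diffuse in a periodic box surrounding a 3D Gaussian
#' detection volume (lateral \eqn{1/e^2} radius `w0_um`, axial radius
#' `kappa * w0_um`); per-axis displacement per step has variance
#' \eqn{2 D \, dt}. Each molecule contributes
#' \eqn{B \exp(-2(x^2+y^2)/w_0^2 - 2z^2/z_0^2)} counts/s, and observed
#' counts per bin are Poisson draws around the accumulated rate plus
#' background. The box spans `box_factor * w0` laterally and
#' `box_factor * kappa * w0` axially (>= 8 keeps periodic edge effects
#' below 1% of the detection integral); the molecule number is a Poisson
#' draw at the target concentration times the box volume. The trace is a
#' pure function of the seed.
#'
#' @param concentration_M molar concentration.
#' @param D_um2s diffusion coefficient (µm²/s).
#' @param w0_um lateral \eqn{1/e^2} radius (µm).
#' @param kappa axial-to-lateral aspect ratio.
#' @param brightness_cps detected counts/s per molecule at the focus
#'   center.
#' @param background_cps uniform background count rate (counts/s).
#' @param duration_s trace duration (s).
#' @param dt_s time-bin width (s); the per-step RMS displacement
#'   \eqn{\sqrt{2 D dt}} must not exceed `w0/4`.
#' @param seed integer seed.
#' @param box_factor box size in units of `w0` (lateral) and
#'   `kappa * w0` (axial); minimum 8.
#' @return an `fcs_trace`: integer `counts` per bin, `dt_s`, and a
#'   `params` provenance list (including the drawn molecule number and
#'   the box volume).
#' @export
simulate_fcs_photons <- function(concentration_M, D_um2s, w0_um, kappa,
                                 brightness_cps, background_cps = 0,
                                 duration_s = 20, dt_s = 5e-6,
                                 seed = 1L, box_factor = 8) {
  stopifnot(concentration_M > 0, D_um2s > 0, w0_um > 0, kappa >= 1,
            brightness_cps >= 0, background_cps >= 0, duration_s > 0,
            dt_s > 0)
  if (box_factor < 8)
    stop_sflim("box_factor must be >= 8 to keep edge effects negligible",
               "sflim_domain_error")
  sigma_step <- sqrt(2 * D_um2s * dt_s)
  if (sigma_step > w0_um / 4)
    stop_sflim(sprintf(
      "dt too coarse: per-step displacement %.3g um exceeds w0/4 = %.3g um",
      sigma_step, w0_um / 4), "sflim_domain_error")
  Lx <- box_factor * w0_um
  Lz <- box_factor * kappa * w0_um
  V_box_L <- Lx * Lx * Lz * 1e-15           # um^3 -> litres
  n_steps <- as.integer(round(duration_s / dt_s))
  seeds <- derive_seeds(seed, 3L)
  n_mol <- with_seed(seeds[1],
                     rpois(1, concentration_M * AVOGADRO * V_box_L))
  lambda <- rep(0, n_steps)
  if (n_mol > 0 && brightness_cps > 0)
    lambda <- .fcs_brownian_intensity(
      n_steps, n_mol, sigma_step, Lx, Lx, Lz,
      w0_um, kappa * w0_um, brightness_cps * dt_s, seeds[2])
  counts <- with_seed(seeds[3],
                      rpois(n_steps, lambda + background_cps * dt_s))
  structure(list(counts = as.integer(counts), dt_s = dt_s,
                 params = list(concentration_M = concentration_M,
                               D_um2s = D_um2s, w0_um = w0_um,
                               kappa = kappa,
                               brightness_cps = brightness_cps,
                               background_cps = background_cps,
                               duration_s = duration_s,
                               box_factor = box_factor,
                               n_molecules = n_mol,
                               V_box_L = V_box_L, seed = seed)),
            class = "fcs_trace")
}

#' @export
print.fcs_trace <- function(x, ...) {
  cat(sprintf(
    "FCS trace: %.3g s at %.3g us bins, mean rate %.3g kHz (%d molecules)\n",
    length(x$counts) * x$dt_s, x$dt_s * 1e6,
    mean(x$counts) / x$dt_s / 1e3, x$params$n_molecules))
  invisible(x)
}
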