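#' Multi-tau autocorrelation of an intensity trace
#'
#' Computes the normalized intensity autocorrelation
#' \eqn{G(\tau) = \langle \delta F(t)\, \delta F(t+\tau) \rangle /
#' \langle F \rangle^2} on a quasi-logarithmic multi-tau lag grid: 8 lags
#' per level, with the trace binned 2x coarser at each subsequent level
#' (lags 5--8 of each coarse level extend the grid). Symmetric
#' normalization is used per lag: the means in the denominator are taken
#' over the left and right overlapping windows, which removes the leading
#' finite-trace bias.
#'
#' @param trace binned photon counts (an `fcs_trace` or numeric vector).
#' @param dt_s bin width in seconds (taken from the trace object when
#'   omitted).
#' @param n_per_level lags per level (default 8).
#' @param max_lag_s optional largest lag to evaluate (default: 1/8 of the
#'   trace duration).
#' @return an `fcs_curve`: data frame with `lag_s`, `G` and `n_pairs`
#'   (averaged products per lag).
#' @export
autocorrelate <- function(trace, dt_s = NULL, n_per_level = 8L,
                          max_lag_s = NULL) {
  if (inherits(trace, "fcs_trace")) {
    dt_s <- dt_s %||% trace$dt_s
    trace <- trace$counts
  }
  stopifnot(!is.null(dt_s), dt_s > 0)
  x <- as.numeric(trace)
  n <- length(x)
  if (n < 4L * n_per_level)
    stop_sflim("trace too short for the requested lag grid",
               "sflim_domain_error")
  if (mean(x) == 0)
    stop_sflim("zero-mean trace cannot be normalized", "sflim_domain_error")
  max_lag_s <- max_lag_s %||% (n * dt_s / 8)
  lag_s <- numeric(0); G <- numeric(0); npairs <- numeric(0)
  level <- 0L
  dt_lvl <- dt_s
  repeat {
    lags <- if (level == 0L) seq_len(n_per_level)
            else (n_per_level %/% 2L + 1L):n_per_level
    for (k in lags) {
      tau <- k * dt_lvl
      if (tau > max_lag_s || k >= length(x)) next
      nl <- length(x) - k
      left <- x[seq_len(nl)]
      right <- x[k + seq_len(nl)]
      ml <- mean(left); mr <- mean(right)
      if (ml <= 0 || mr <= 0) next
      lag_s <- c(lag_s, tau)
      G <- c(G, mean(left * right) / (ml * mr) - 1)
      npairs <- c(npairs, nl)
    }
    ## coarsen by 2 for the next level
    nn <- length(x) %/% 2L
    if (nn < 2L * n_per_level) break
    x <- x[seq_len(2L * nn)]
    x <- x[seq(1L, 2L * nn, by = 2L)] + x[seq(2L, 2L * nn, by = 2L)]
    dt_lvl <- dt_lvl * 2
    level <- level + 1L
    if (n_per_level * dt_lvl > max_lag_s) break
  }
  structure(list(curve = data.frame(lag_s = lag_s, G = G,
                                    n_pairs = npairs),
                 dt_s = dt_s, duration_s = n * dt_s),
            class = "fcs_curve")
}

#' @export
print.fcs_curve <- function(x, ...) {
  cat(sprintf("FCS curve: %d lags from %.3g to %.3g s (trace %.3g s)\n",
              nrow(x$curve), min(x$curve$lag_s), max(x$curve$lag_s),
              x$duration_s))
  invisible(x)
}

#' Single-species 3D diffusion FCS model
#'
#' \deqn{G(\tau) = \frac{1}{N} \left(1 + \frac{\tau}{\tau_D}\right)^{-1}
#'   \left(1 + \frac{\tau}{\kappa^2 \tau_D}\right)^{-1/2}}
#' for `N` molecules in the effective volume, diffusion time
#' \eqn{\tau_D} and axial-to-lateral aspect ratio \eqn{\kappa}.
#' `G(0) = 1/N`; the model decreases strictly to 0.
#'
#' @param tau_s lag times (s).
#' @param N mean molecule number in the effective volume.
#' @param tau_D_s diffusion time (s).
#' @param kappa aspect ratio (>= 1).
#' @return model values.
#' @export
fcs_model_3d <- function(tau_s, N, tau_D_s, kappa) {
  (1 / N) / ((1 + tau_s / tau_D_s) *
               sqrt(1 + tau_s / (kappa^2 * tau_D_s)))
}

#' Fit the 3D diffusion model to an FCS curve
#'
#' Weighted least squares (weights = number of averaged lag products,
#' i.e. inverse-variance up to the photon noise scale) via
#' Levenberg--Marquardt. `kappa` may be fixed to a calibration value —
#' the usual practice, since curves constrain it poorly.
#'
#' @param curve an `fcs_curve` (or data frame `lag_s`, `G`, optionally
#'   `n_pairs`).
#' @param fix_kappa numeric to fix the aspect ratio, or `NULL` to fit it.
#' @param max_lag_s optionally restrict fitted lags.
#' @return an `fcs_fit`: `N`, `tau_D_s`, `kappa`, `kappa_fixed`,
#'   standard errors (where fitted) and the fit object.
#' @export
fit_fcs <- function(curve, fix_kappa = NULL, max_lag_s = NULL) {
  df <- if (inherits(curve, "fcs_curve")) curve$curve else as.data.frame(curve)
  if (!is.null(max_lag_s)) df <- df[df$lag_s <= max_lag_s, ]
  df <- df[is.finite(df$G), ]
  if (nrow(df) < 10L)
    stop_sflim("need at least 10 lags to fit the diffusion model",
               "sflim_fit_error")
  w <- if ("n_pairs" %in% names(df)) df$n_pairs else rep(1, nrow(df))
  g0 <- max(mean(df$G[seq_len(min(3L, nrow(df)))]), 1e-6)
  N0 <- 1 / g0
  half <- df$lag_s[which.min(abs(df$G - g0 / 2))]
  start <- list(N = N0, tau_D_s = max(half, df$lag_s[2]))
  lower <- c(1e-6, 1e-9)
  upper <- c(1e9, 1e3)
  if (is.null(fix_kappa)) {
    start$kappa <- 5
    lower <- c(lower, 1)
    upper <- c(upper, 100)
    fit <- minpack.lm::nlsLM(
      G ~ fcs_model_3d(lag_s, N, tau_D_s, kappa),
      data = df, start = start, weights = w,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    kappa <- as.numeric(fix_kappa)
    fit <- minpack.lm::nlsLM(
      G ~ fcs_model_3d(lag_s, N, tau_D_s, kappa),
      data = df, start = start, weights = w,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  if (!fit$convInfo$isConv)
    stop_sflim(sprintf("FCS fit did not converge: %s",
                       fit$convInfo$stopMessage), "sflim_fit_error")
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  structure(list(N = unname(est["N"]),
                 tau_D_s = unname(est["tau_D_s"]),
                 kappa = if (is.null(fix_kappa)) unname(est["kappa"])
                         else as.numeric(fix_kappa),
                 kappa_fixed = !is.null(fix_kappa),
                 se = se, fit = fit),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("FCS fit: N = %.3g, tau_D = %.4g ms, kappa = %.3g%s\n",
              x$N, x$tau_D_s * 1e3, x$kappa,
              if (x$kappa_fixed) " (fixed)" else ""))
  invisible(x)
}

#' Confocal volume calibration from a reference dye
#'
#' Given a fitted diffusion time for a dye of known diffusion
#' coefficient, the lateral \eqn{1/e^2} radius is
#' \eqn{w_0 = \sqrt{4 D \tau_D}}, the axial radius \eqn{z_0 = \kappa w_0},
#' and the effective volume \eqn{V_{eff} = \pi^{3/2} w_0^2 z_0}.
#'
#' @param fit an `fcs_fit` (or list with `tau_D_s` and `kappa`).
#' @param D_ref_um2s reference diffusion coefficient in µm²/s.
#' @return an `fcs_calibration`: `w0_um`, `z0_um`, `kappa`, `V_eff_fl`
#'   (1 fl = 1 µm³), `D_ref_um2s`.
#' @export
#' @examples
#' calibrate(list(tau_D_s = 61.0e-6, kappa = 5.6), D_ref_um2s = 400)
calibrate <- function(fit, D_ref_um2s) {
  stopifnot(D_ref_um2s > 0, fit$tau_D_s > 0, fit$kappa >= 1)
  w0 <- sqrt(4 * D_ref_um2s * fit$tau_D_s) # µm, since D µm²/s * s
  z0 <- fit$kappa * w0
  structure(list(w0_um = w0, z0_um = z0, kappa = fit$kappa,
                 V_eff_fl = pi^1.5 * w0^2 * z0,
                 D_ref_um2s = D_ref_um2s),
            class = "fcs_calibration")
}

#' @export
print.fcs_calibration <- function(x, ...) {
  cat(sprintf(
    "FCS calibration: w0 = %.3g um, z0 = %.3g um (kappa %.3g), V_eff = %.3g fl\n",
    x$w0_um, x$z0_um, x$kappa, x$V_eff_fl))
  invisible(x)
}

#' Molar concentration from molecule number and effective volume
#'
#' \eqn{C = N / (N_A V_{eff})} with Avogadro's number \eqn{N_A} and
#' \eqn{V_{eff}} in femtolitres.
#'
#' @param N mean molecules in the effective volume (> 0).
#' @param V_eff_fl effective volume in fl (> 0).
#' @return molar concentration (mol/L).
#' @export
#' @examples
#' concentration(30.3, 0.95) * 1e9   # ~53 nM
concentration <- function(N, V_eff_fl) {
  stopifnot(N > 0, V_eff_fl > 0)
  N / (AVOGADRO * V_eff_fl * 1e-15)
}

AVOGADRO <- 6.02214076e23

## Inverse: molecules in V_eff at a molar concentration.
molecules_in_volume <- function(conc_M, V_fl) {
  conc_M * AVOGADRO * V_fl * 1e-15
}

#' Export an FCS curve and fit as CSV / JSON
#'
#' @param curve an `fcs_curve`.
#' @param path CSV output path for the lag/G table.
#' @param fit optional `fcs_fit`; adds fitted model values to the table.
#' @return the table, invisibly.
#' @export
write_fcs_curve <- function(curve, path, fit = NULL) {
  df <- curve$curve
  if (!is.null(fit))
    df$G_fit <- fcs_model_3d(df$lag_s, fit$N, fit$tau_D_s, fit$kappa)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_fcs_curve
#' @param calib an `fcs_calibration`.
#' @export
write_calibration_json <- function(calib, path) {
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
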