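#' Periodic multi-exponential decay shapes
#'
#' Fluorescence decays under pulsed excitation at repetition period `T`
#' reach a periodic steady state: the observed profile of a component with
#' lifetime \eqn{\tau} is the periodic sum
#' \eqn{u(t) = \sum_{k \ge 0} e^{-(t + kT)/\tau} = e^{-t/\tau} / (1 - e^{-T/\tau})}
#' for \eqn{t \in [0, T)}, so incomplete decays wrap into the following
#' excitation epoch. `periodic_exponential()` samples this (unit pre-pulse
#' amplitude) profile at the TCSPC bin centers; `decay_shape()` convolves a
#' multi-exponential mixture circularly with an epoch's IRF and normalizes
#' it to a per-bin probability distribution over the full sync period.
#'
#' @param tau_ns lifetime in ns (> 0).
#' @param config an `sflim_config`.
#' @return numeric vector of length `config$n_tcspc`.
#' @keywords internal
periodic_exponential <- function(tau_ns, config) {
  if (tau_ns <= 0)
    stop_sflim("lifetime must be positive", "sflim_domain_error")
  period <- sync_period_ns(config)
  t <- tcspc_bin_centers(config)
  exp(-t / tau_ns) / (1 - exp(-period / tau_ns))
}

## Normalize decay components to a data.frame(fraction, tau_ns).
as_components <- function(components) {
  if (is.numeric(components) && is.null(dim(components)))
    components <- data.frame(fraction = rep(1 / length(components),
                                            length(components)),
                             tau_ns = as.numeric(components))
  components <- as.data.frame(components)
  names(components)[1:2] <- c("fraction", "tau_ns")
  if (any(components$tau_ns <= 0))
    stop_sflim("lifetimes must be positive", "sflim_domain_error")
  if (any(components$fraction < 0) || sum(components$fraction) <= 0)
    stop_sflim("amplitude fractions must be nonnegative with positive sum",
               "sflim_domain_error")
  components$fraction <- components$fraction / sum(components$fraction)
  components
}

#' Normalized decay shape of an emitting species in one epoch
#'
#' @param components decay components: a vector of lifetimes (equal
#'   amplitude fractions) or a data frame with columns `fraction`
#'   (amplitude fraction) and `tau_ns`.
#' @param epoch excitation epoch index (1-based).
#' @param config an `sflim_config`.
#' @param irf an `sflim_irf` (defaults to the config's Gaussian IRF).
#' @return per-bin probabilities over the full sync period (sum 1); the
#'   excited-state emission starts at the epoch's pulse offset and wraps
#'   circularly.
#' @export
decay_shape <- function(components, epoch, config, irf = gaussian_irf(config)) {
  comp <- as_components(components)
  base <- rep(0, config$n_tcspc)
  for (i in seq_len(nrow(comp)))
    base <- base + comp$fraction[i] * periodic_exponential(comp$tau_ns[i], config)
  out <- circular_convolve(base, irf$h[epoch, ])
  out / sum(out)
}

#' Expected TCSPC histogram of a reconvolved multi-exponential decay
#'
#' The forward model used by the decay fitter: periodic multi-exponential
#' components (unit-amplitude profiles from [periodic_exponential()])
#' scaled by their amplitudes, circularly convolved with the selected
#' epoch's IRF, optionally time-shifted, plus a flat background — evaluated
#' on the epoch's own TCSPC bins. The model is linear in the amplitudes
#' and in the background.
#'
#' @param components data frame with columns `amplitude` (counts per bin
#'   at the pulse, >= 0) and `tau_ns`, or a numeric vector of lifetimes
#'   with unit amplitudes.
#' @param background flat background counts per bin.
#' @param shift_ns circular time shift applied to the IRF (ns).
#' @param irf an `sflim_irf`.
#' @param epoch epoch index whose bins are returned.
#' @param config an `sflim_config`.
#' @return expected counts per bin, length `bins_per_epoch(config)`.
#' @export
#' @examples
#' cfg <- sflim_config(n_tcspc = 256L)
#' m <- reconvolved_model(data.frame(amplitude = 100, tau_ns = 2),
#'                        background = 1, irf = delta_irf(cfg),
#'                        epoch = 1, config = cfg)
reconvolved_model <- function(components, background = 0, shift_ns = 0,
                              irf, epoch = 1L, config) {
  if (is.numeric(components) && is.null(dim(components)))
    components <- data.frame(amplitude = rep(1, length(components)),
                             tau_ns = as.numeric(components))
  components <- as.data.frame(components)
  names(components)[1:2] <- c("amplitude", "tau_ns")
  if (any(components$tau_ns <= 0))
    stop_sflim("lifetimes must be positive", "sflim_domain_error")
  if (any(components$amplitude < 0))
    stop_sflim("amplitudes must be nonnegative", "sflim_domain_error")
  stopifnot(background >= 0)
  full <- rep(0, config$n_tcspc)
  for (i in seq_len(nrow(components)))
    full <- full + components$amplitude[i] *
      periodic_exponential(components$tau_ns[i], config)
  kern <- irf$h[epoch, ]
  if (shift_ns != 0) kern <- circular_shift(kern, shift_ns, config)
  full <- circular_convolve(full, kern)
  epoch_bins(full, epoch, config) + background
}

## Extract one epoch's bins from a full-period vector.
epoch_bins <- function(full, epoch, config) {
  nb <- bins_per_epoch(config)
  full[((epoch - 1L) * nb + 1L):(epoch * nb)]
}
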