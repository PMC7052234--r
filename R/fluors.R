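#' Fluorophore and FRET-pair specifications
#'
#' A fluorophore is modelled by a Gaussian emission spectrum (center and
#' width in nm), a mono- or multi-exponential fluorescence decay
#' (amplitude fractions and lifetimes), a per-laser relative excitation
#' efficiency, and a brightness (mean detected photons per unit label
#' density per unit exposure). A FRET pair couples a donor and an acceptor
#' on cross-labelled secondary antibodies: transfer efficiency `E` quenches
#' the donor (lifetimes scaled by `1 - E`), and a fraction
#' `sensitized_fraction` of the transferred excitations yields detected
#' sensitized acceptor photons; the acceptor is additionally excited
#' directly through its own excitation efficiencies.
#'
#' @param name label for reports.
#' @param emission_center_nm,emission_sigma_nm Gaussian emission spectrum
#'   parameters (nm).
#' @param decay lifetimes in ns (vector, equal amplitude fractions) or a
#'   data frame with columns `fraction` and `tau_ns`.
#' @param excitation relative excitation probability per laser, each in
#'   \eqn{[0, 1]}, at least one positive.
#' @param brightness mean detected photons per unit density per unit
#'   exposure.
#' @return a `fluorophore` / `fret_pair` object.
#' @export
#' @examples
#' donor <- fluorophore("A488", 519, 14, decay = 3.84,
#'                      excitation = c(1, 0.02))
#' pair <- fret_pair(donor, fluorophore_preset("alexa546"),
#'                   efficiency = 0.171875)
fluorophore <- function(name, emission_center_nm, emission_sigma_nm,
                        decay, excitation, brightness = 1) {
  stopifnot(is_scalar_number(emission_center_nm),
            is_scalar_number(emission_sigma_nm), emission_sigma_nm > 0,
            is.numeric(excitation), all(excitation >= 0),
            all(excitation <= 1), any(excitation > 0),
            is_scalar_number(brightness), brightness >= 0)
  structure(list(
    name = as.character(name),
    emission_center_nm = emission_center_nm,
    emission_sigma_nm = emission_sigma_nm,
    decay = as_components(decay),
    excitation = as.numeric(excitation),
    brightness = brightness
  ), class = "fluorophore")
}

#' @rdname fluorophore
#' @param donor,acceptor `fluorophore` objects.
#' @param efficiency FRET efficiency `E` in \eqn{[0, 1)}.
#' @param sensitized_fraction share of transferred donor excitations that
#'   yield detected acceptor photons, in \eqn{[0, 1]}.
#' @export
fret_pair <- function(donor, acceptor, efficiency,
                      sensitized_fraction = 0.5, name = NULL) {
  stopifnot(inherits(donor, "fluorophore"), inherits(acceptor, "fluorophore"),
            is_scalar_number(efficiency),
            is_scalar_number(sensitized_fraction),
            sensitized_fraction >= 0, sensitized_fraction <= 1)
  if (efficiency < 0 || efficiency >= 1)
    stop_sflim("FRET efficiency must lie in [0, 1)", "sflim_domain_error")
  structure(list(
    name = name %||% paste0(donor$name, ":", acceptor$name),
    donor = donor,
    acceptor = acceptor,
    efficiency = efficiency,
    sensitized_fraction = sensitized_fraction
  ), class = "fret_pair")
}

#' @export
print.fluorophore <- function(x, ...) {
  cat(sprintf("fluorophore '%s': em %g +/- %g nm, tau {%s} ns, brightness %g\n",
              x$name, x$emission_center_nm, x$emission_sigma_nm,
              paste(signif(x$decay$tau_ns, 3), collapse = ", "),
              x$brightness))
  invisible(x)
}

#' @export
print.fret_pair <- function(x, ...) {
  cat(sprintf("FRET pair '%s': E = %.3f, sensitized fraction %.2f\n",
              x$name, x$efficiency, x$sensitized_fraction))
  invisible(x)
}

#' Built-in fluorophore analogues
#'
#' Gaussian-spectrum analogues of the Alexa dyes carried by the secondary
#' antibodies in the modelled experiments, for a two-laser 485/561 nm
#' system. Emission centers/widths approximate the dyes' spectra; the
#' Alexa488 lifetime (3.84 ns) and the Alexa555 lifetime (0.93 ns) are the
#' antibody-conjugate values used throughout the package's scenarios, and
#' the Alexa546 conjugate is modelled mono-exponentially at 4.0 ns.
#'
#' @param name one of `"alexa488"`, `"alexa546"`, `"alexa555"`.
#' @param brightness detected photons per unit density per unit exposure.
#' @return a `fluorophore`.
#' @export
fluorophore_preset <- function(name = c("alexa488", "alexa546", "alexa555"),
                               brightness = 1) {
  switch(match.arg(name),
    alexa488 = fluorophore("alexa488", 519, 14, decay = 3.84,
                           excitation = c(1.0, 0.02), brightness = brightness),
    alexa546 = fluorophore("alexa546", 573, 16, decay = 4.0,
                           excitation = c(0.10, 0.90), brightness = brightness),
    alexa555 = fluorophore("alexa555", 567, 18, decay = 0.93,
                           excitation = c(0.08, 1.0), brightness = brightness)
  )
}

#' Emission probability per spectral channel
#'
#' Integrates the Gaussian emission density over each spectral channel
#' interval, applies the notch-filter attenuation to the channel containing
#' the notch center (if the configuration defines one), and renormalizes to
#' a probability vector.
#'
#' @param fluor a `fluorophore`.
#' @param config an `sflim_config`.
#' @return probability vector of length `config$n_spectral` (sum 1).
#' @export
emission_channel_probs <- function(fluor, config) {
  stopifnot(inherits(fluor, "fluorophore"))
  edges <- spectral_channel_edges(config)
  p <- diff(pnorm(edges, fluor$emission_center_nm, fluor$emission_sigma_nm))
  if (!is.null(config$notch)) {
    ch <- spectral_channel_of(config$notch[1], config)
    if (!is.na(ch)) p[ch] <- p[ch] * config$notch[2]
  }
  if (sum(p) <= 1e-12)
    stop_sflim(sprintf(
      "emission spectrum of '%s' has no overlap with the detection range",
      fluor$name), "sflim_domain_error")
  p / sum(p)
}

#' Donor specification under FRET quenching
#'
#' FRET opens a nonradiative de-excitation channel: every donor lifetime
#' component is scaled by `1 - E` and the donor brightness (photons
#' emitted by the donor itself) drops by the same factor; amplitude
#' fractions are unchanged.
#'
#' @param donor a `fluorophore`.
#' @param efficiency FRET efficiency `E` in \eqn{[0, 1)}.
#' @return the quenched `fluorophore`.
#' @export
#' @examples
#' d <- fluorophore_preset("alexa488")
#' fret_modified_donor(d, 0.171875)$decay$tau_ns   # 3.84 * (1 - E) = 3.18
fret_modified_donor <- function(donor, efficiency) {
  stopifnot(inherits(donor, "fluorophore"))
  if (efficiency < 0 || efficiency >= 1)
    stop_sflim("FRET efficiency must lie in [0, 1)", "sflim_domain_error")
  out <- donor
  out$decay$tau_ns <- donor$decay$tau_ns * (1 - efficiency)
  out$brightness <- donor$brightness * (1 - efficiency)
  out$name <- paste0(donor$name, "(FRET)")
  out
}

#' Sensitized acceptor emission decay shape
#'
#' After energy transfer the acceptor population follows the two-rate
#' kinetics \eqn{e^{-t/\tau_A} - e^{-t/\tau_{DA}}} (rise limited by the
#' slower of transfer feeding and acceptor decay). The shape is built from
#' the periodic steady-state sums of both terms, circularly convolved with
#' the epoch's IRF and normalized to a per-bin probability distribution
#' over the sync period.
#'
#' @param tau_DA_ns quenched donor lifetime (feeding time constant), ns.
#' @param tau_A_ns acceptor lifetime, ns.
#' @param epoch excitation epoch index.
#' @param config an `sflim_config`.
#' @param irf an `sflim_irf`.
#' @return per-bin probabilities over the full sync period (sum 1).
#' @export
sensitized_decay_shape <- function(tau_DA_ns, tau_A_ns, epoch, config,
                                   irf = gaussian_irf(config)) {
  if (tau_DA_ns <= 0 || tau_A_ns <= 0)
    stop_sflim("lifetimes must be positive", "sflim_domain_error")
  if (tau_DA_ns == tau_A_ns)
    stop_sflim(paste("equal feeding and acceptor lifetimes: use the",
                     "t*exp(-t/tau) limit form instead"),
               "sflim_domain_error")
  d <- periodic_exponential(tau_A_ns, config) -
    periodic_exponential(tau_DA_ns, config)
  if (sum(d) < 0) d <- -d
  out <- circular_convolve(d, irf$h[epoch, ])
  out[out < 0] <- 0
  out / sum(out)
}

## Emitting-species decomposition of a label: for each (laser, species)
## combination, a weight (relative detected photons), a spectral
## probability vector and a full-period time profile. The shared currency
## of ground_truth_pattern() and label_brightness().
label_species <- function(label, config, irf) {
  if (inherits(label, "fluorophore")) {
    specs <- list()
    q <- emission_channel_probs(label, config)
    for (e in seq_len(n_epochs(config))) {
      if (label$excitation[e] <= 0) next
      specs[[length(specs) + 1L]] <- list(
        weight = label$excitation[e] * label$brightness,
        spectral = q,
        temporal = decay_shape(label$decay, e, config, irf))
    }
    return(specs)
  }
  if (!inherits(label, "fret_pair"))
    stop_sflim("label must be a fluorophore or fret_pair",
               "sflim_domain_error")
  E <- label$efficiency
  sf <- label$sensitized_fraction
  dq <- fret_modified_donor(label$donor, E)
  q_d <- emission_channel_probs(dq, config)
  q_a <- emission_channel_probs(label$acceptor, config)
  tau_A <- lifetime_summary(
    data.frame(amplitude = label$acceptor$decay$fraction,
               tau_ns = label$acceptor$decay$tau_ns))$tau_int
  specs <- list()
  for (e in seq_len(n_epochs(config))) {
    exc_d <- label$donor$excitation[e] * label$donor$brightness
    if (exc_d > 0) {
      ## quenched donor emission
      specs[[length(specs) + 1L]] <- list(
        weight = exc_d * (1 - E),
        spectral = q_d,
        temporal = decay_shape(dq$decay, e, config, irf))
      ## sensitized acceptor emission, fed by each quenched donor component
      if (E * sf > 0) {
        for (i in seq_len(nrow(dq$decay))) {
          tau_feed <- dq$decay$tau_ns[i]
          shape <- if (abs(tau_feed - tau_A) < 1e-9)
            decay_shape(tau_A, e, config, irf)
          else
            sensitized_decay_shape(tau_feed, tau_A, e, config, irf)
          specs[[length(specs) + 1L]] <- list(
            weight = exc_d * E * sf * dq$decay$fraction[i],
            spectral = q_a,
            temporal = shape)
        }
      }
    }
    ## direct acceptor excitation
    exc_a <- label$acceptor$excitation[e] * label$acceptor$brightness
    if (exc_a > 0)
      specs[[length(specs) + 1L]] <- list(
        weight = exc_a,
        spectral = q_a,
        temporal = decay_shape(label$acceptor$decay, e, config, irf))
  }
  specs
}

#' Total brightness of a label
#'
#' Mean detected photons per unit density per unit exposure, summed over
#' lasers and emitting species (for a FRET pair: quenched donor emission,
#' sensitized acceptor emission and directly excited acceptor emission).
#'
#' @param label a `fluorophore` or `fret_pair`.
#' @param config an `sflim_config`.
#' @return scalar brightness.
#' @export
label_brightness <- function(label, config) {
  irf <- delta_irf(config)  # weights do not depend on the IRF
  sum(vapply(label_species(label, config, irf), `[[`, numeric(1), "weight"))
}

#' Exact reference pattern of a label
#'
#' Builds the ground-truth joint probability distribution over
#' (epoch x spectral channel x TCSPC bin) for a labelled species: for each
#' laser, the excitation-efficiency-weighted mixture of (decay shape x
#' emission channel probabilities), with the full-period decay profiles cut
#' into the excitation epochs so that long decays and sensitized emission
#' wrap where the physics puts them. For a FRET pair this combines quenched
#' donor emission, sensitized acceptor emission (weight
#' `efficiency * sensitized_fraction`) and direct acceptor excitation —
#' including the acceptor-band mass in the donor epoch that fingerprints
#' FRET.
#'
#' @param label a `fluorophore` or `fret_pair`.
#' @param config an `sflim_config`.
#' @param irf an `sflim_irf`.
#' @return an `sflim_pattern` whose array `p` has dimensions
#'   `(n_epochs, n_spectral, bins_per_epoch)` and sums to 1.
#' @export
ground_truth_pattern <- function(label, config, irf = gaussian_irf(config)) {
  specs <- label_species(label, config, irf)
  ne <- n_epochs(config)
  ns <- config$n_spectral
  nb <- bins_per_epoch(config)
  p <- array(0, dim = c(ne, ns, nb))
  for (sp in specs) {
    for (e in seq_len(ne)) {
      seg <- epoch_bins(sp$temporal, e, config)
      ## outer product spectral x time for this epoch slice
      p[e, , ] <- p[e, , ] + sp$weight * outer(sp$spectral, seg)
    }
  }
  reference_pattern(p / sum(p), label = label$name,
                    config = config,
                    meta = list(source = "ground_truth"))
}
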