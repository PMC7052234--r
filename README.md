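# sflimfret

Spectral FLIM-FRET analysis of antibody cross-labelling, on synthetic
data: simulation of multi-dimensional photon histogram cubes
(excitation epoch × spectral channel × TCSPC time), Poisson
maximum-likelihood reconvolution lifetime fitting, reference-pattern
unmixing, bleed-through quantification, and FCS concentration
calibration.

## The problem

In indirect immunofluorescence, secondary antibodies from overlapping
host species can bind *each other* ("cross-labelling"), placing two
fluorophores within Förster distance. The cross-labelled structure emits
in both fluorophores' bands and shows up as a false positive in every
bandpass channel — filter choice cannot fix it. But the cross-label has
distinctive photophysics: Förster resonance energy transfer (FRET)
shortens the donor lifetime (here from 3.84 ns to 3.18 ns,
Δτ_int = 0.66 ns) and adds sensitized acceptor emission under donor
excitation. An instrument that records excitation pulse (pulsed
interleaved excitation at 40 MHz, 485/561 nm), emission wavelength
(8 channels × 18.8 nm over 490–640 nm) and TCSPC arrival time per photon
sees a unique joint signature for each species.

The analysis core treats each labelled species as a **reference
pattern** — a probability distribution p_jk over all (epoch, channel,
time) bins — and recovers per-pixel photon contributions f_j ≥ 0 by
maximizing the Poisson likelihood of μ_k = Σ_j f_j p_jk with
multiplicative (Richardson–Lucy-type) EM updates

    f_j ← f_j · Σ_k p_jk n_k / μ_k,

which are monotone in likelihood and conserve counts (Σ f_j = Σ n_k) at
convergence. Lifetimes come from bi-exponential reconvolution fits of
TCSPC histograms under the same Poisson model, summarized as the
intensity-weighted mean τ_int = Σ a τ² / Σ a τ. Antibody concentrations
come from fluorescence correlation spectroscopy:
C = N / (N_A·V_eff) with V_eff = π^{3/2} w₀² z₀ calibrated from a
reference dye.

## Worked example

Quantify donor quenching exactly as in a solution FRET measurement: two
10⁶-photon decay histograms at the unquenched/quenched lifetimes, both
fitted by bi-exponential Poisson reconvolution:

```r
library(sflimfret)
ex <- delta_tau_experiment(seed = 1L)   # tau 3.84 ns vs 3.18 ns
ex$fret
#> FRET: tau_D = 3.835 ns, tau_DA = 3.182 ns, delta tau_int = 0.653 ns, E = 0.170
ex$fit_quenched
#> decay fit: 2 component(s), 1,009,191 photons, chi2_red = 1.028
#>   a =   7821.079  tau = 3.183 ns (+/- 0.009)
#>   a =     25.541  tau = 0.6934 ns (+/- 1.1)
#>   background 20.02 counts/bin; tau_int = 3.182 ns, tau_amp = 3.175 ns
```

The recovered Δτ_int (0.653 ns here) measures the FRET-induced lifetime
drop; its fluctuation across seeds is a few hundredths of a ns at 10⁶
photons. The full imaging pipeline runs the same way:

```r
ex <- triple_antigen_experiment(seed = 1L)  # simulate, extract patterns,
round(100 * ex$B, 2)                        # unmix, residual crosstalk (%)
```

rows are pure structures, columns unmixed channels; off-diagonal entries
are the bleed-through percentages. And the FCS stack:

```r
fcs <- fcs_concentration_experiment(seed = 1L)  # 53 nM target
fcs$concentration_M_hat * 1e9                   # recovered nM
```

A command-line workbench (`exec/sflim`) exposes the same operations as
subcommands (`simulate`, `channel-mode`, `extract-pattern`, `unmix`,
`fit-decay`, `fret`, `bleedthrough`, `fcs-sim`, `fcs-fit`) over HDF5
cubes/patterns/traces, multi-page TIFF images and CSV/JSON tables, with
a manifest JSON (seed, configuration hash, versions) beside every
output. Demo scenes live in `inst/extdata/*.yaml`.

See `vignettes/sflim-fret-methods.Rmd` for the full model description,
parameter choices, and limitations.

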