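---
title: "Oxygen transmittance compensation for proximal-sensing SIF retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oxygen transmittance compensation for proximal-sensing SIF retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxsif)
```

## The measurement problem

Sun-induced chlorophyll fluorescence (SIF) is a weak emission
(~1 mW m^-2^ sr^-1^ nm^-1^ in the far-red) superimposed on reflected sunlight
that is two orders of magnitude brighter. Passive retrievals exploit the
telluric O~2~ absorption bands near 760 nm (O~2~-A) and 687 nm (O~2~-B):
inside an absorption line the reflected component is strongly depleted while
the additive fluorescence is not, so the "in-filling" of the band carries the
SIF signal.

Tower-mounted spectrometers measure the up-welling canopy radiance $L$ and the
down-welling irradiance $E$ some metres *above* the canopy. Over that short
path the O~2~ molecules between canopy and sensor re-absorb part of the
signal exactly where the retrieval looks for it. The toolkit quantifies this
effect and implements the compensation strategies, under the short-path
simplifications: path radiance and spherical-albedo coupling are negligible,
the upward transmittance is dominated by its direct component, and the
surface is Lambertian. The forward model is

$$\bar E = E\,t^\downarrow,\qquad
  \bar L = \rho\,\bar E/\pi + F,\qquad
  L = \bar L\, t^\uparrow,$$

with $\rho$ the surface reflectance, $F$ the SIF emission, and
$t^\downarrow, t^\uparrow$ the short-path transmittances slanted by the solar
and view zenith angles. Overbars denote canopy-level quantities.

Every spectrometer delivers its signal through an instrument spectral
response function (ISRF); we write $\langle\cdot\rangle$ for
convolution-plus-sampling at the channel centres. The central mathematical
fact the toolkit is built around is that channelisation and multiplication do
not commute:
$\langle a\rangle\langle b\rangle \neq \langle a b\rangle$
whenever both factors have structure inside a channel. Correcting a
channelised radiance by a channelised transmittance
($\langle L\rangle/\langle t^\uparrow\rangle$) therefore leaves a
resolution-dependent error even when $t^\uparrow$ is known exactly.

## Retrieval methods implemented

* **Direct isolation** (reference experiments): $F = L/t^\uparrow - \bar E\rho/\pi$
  and its three uncorrected/sensor-level variants, assuming $\rho$ known.
* **FLD family**: with an in-band channel (760.6 nm, the band bottom) and
  out-of-band channels,
  $$F=\frac{\alpha_R E_{out} \bar L_{in}-\bar E_{in}\bar L_{out}}
           {\alpha_R \bar E_{out}-\alpha_F \bar E_{in}},$$
  where $\alpha_R=\alpha_F=1$ gives the FLD (one reference channel) and the
  3FLD (two shoulder channels linearly interpolated to the in-band
  wavelength), and $\alpha_R, \alpha_F$ carry the spectral variation of
  $\rho$ and $F$ for the iFLD.
* **O~2~-compensated FLD**: the same estimator evaluated on corrected
  channels, $\bar L = \langle L\rangle/\langle t^\uparrow\rangle$ and
  $\bar E = \langle E\rangle\langle t^\downarrow\rangle$ (the irradiance
  correction is dropped when $E$ is measured at canopy level). The printed
  form of this estimator in parts of the literature multiplies the in-band
  radiance by $t^\uparrow$ instead of dividing; substituting the forward
  model into the FLD shows the division form is the consistent one, so that
  is the default, with `strict_paper = TRUE` reproducing the multiplicative
  form for comparison.
* **Spectral fitting method (SFM)**: least squares over the window
  759.3-767.5 nm with $\rho_{MOD}$ a cubic and $F_{MOD}$ a quadratic
  polynomial in window-scaled wavelength, unweighted residuals, no
  positivity constraint. The sensor-level, first-order O~2~-compensated
  variant minimises
  $L-(E t^\downarrow \rho_{MOD}/\pi+F_{MOD})\,t^\uparrow$ on channelised
  spectra — deliberately committing the convolution inconsistency so its
  bias can be measured.
* **Convolution-consistent SFM**: the airborne-style scheme. The atmospheric
  state is first fitted to the channelised at-sensor irradiance; the fitted
  atmosphere then provides $\bar E$ and $t^\uparrow$ at native resolution,
  and the minimisation compares
  $\langle L\rangle$ with
  $\langle(\bar E \rho_{MOD}/\pi+F_{MOD})\,t^\uparrow\rangle$, rebuilding
  and convolving the forward model at every evaluation. No algebra is ever
  performed between individually convolved spectra.

All SFM variants are linear in the polynomial coefficients; they are solved
with a Levenberg-Marquardt iteration (maximum 200 iterations, relative step
tolerance 1e-10, residual tolerance 1e-12) supplied with the analytic
Jacobian, so convergence is deterministic and the configured first guess
(quadratic fit to a reference SIF spectrum with coefficients distorted by
10%; cubic fit to the apparent reflectance on absorption-free channels) only
matters for reproducibility of the iteration path, not the solution.

## The synthetic atmosphere

No radiative-transfer code or molecular line database is bundled; the
`atmosphere` module generates a deterministic synthetic O~2~ spectroscopy
that reproduces the *band-scale* behaviour of the real bands.

* **Line list.** 120 Lorentzian lines over 759.6-770.4 nm (O~2~-A; 60 over
  686.2-690.8 nm for O~2~-B) arranged as two branch envelopes — a dense
  branch peaking at the 760.6 nm band bottom and a longer decaying branch —
  with alternating doublet strengths and a small deterministic position
  jitter (seed 0). Half-widths scale as $\gamma_0 (p/p_0)(T_0/T)^{0.7}$ and
  strengths as $(T_0/T)^m (p/p_0)^n$ with the band-model exponents below, so
  the empirical band model can represent the engine almost exactly across
  conditions.
* **Reference half-width.** $\gamma_0 = 0.035$ nm. The native grid is
  0.005 nm and every line must be sampled at least four times per half-width
  *including* the narrower lines at column-representative pressure
  (~0.55 atm), which forces $\gamma_0 \gtrsim 0.032$ nm. True O~2~-A
  pressure-broadened half-widths are ~0.003 nm; this order-of-magnitude
  broadening is the single most important idealisation in the package (see
  *Limitations*).
* **Band depth calibration.** The overall strength scale is fixed by
  requiring the 0.22-nm-convolved band minimum over a vertical 15 m path at
  288.15 K / 1013.25 hPa to be 0.95 (O~2~-A; 0.99 for O~2~-B) — the
  channel-scale absorption a line-by-line calculation gives for a short
  sea-level path.
* **Column imprint.** The irradiance arriving at the sensor already carries
  the O~2~ absorption of the whole atmospheric column; without it the
  in-band depletion of $\bar E$ would vanish and every FLD/SFM denominator
  would degenerate. The column is represented by the same line list at
  column-representative conditions (240 K, 0.55 atm — mass-weighted values,
  which also narrow the lines relative to the surface path) with an
  effective absorber path calibrated so the vertical 0.22-nm band-core
  transmittance is 0.15 (O~2~-A) / 0.60 (O~2~-B), deep-core values typical
  of moderate-resolution column spectra. Because the synthetic lines are
  broad, this effective path (~0.5 km) is *not* the physical column; it is
  the value that reproduces the observable band depth.
* **Empirical band model.** $t=\exp[-(10^{C'}(p/p_0)^n(T_0/T)^m U)^a]$ with
  $a=0.5641$, $m=0.9353$, $n=0.1936$, $T_0=273.16$ K, $p_0=1$ atm and
  absorber amount $U=0.7732\times10^{-4} M \rho_a Z$ (atm cm). The
  per-channel coefficients $C'$ are fitted by inverting the law against the
  0.22-nm-convolved engine at reference conditions, which makes the
  round-trip exact there and keeps band model and engine within 2% in-band
  for T in [233, 313] K and p in [950, 1050] hPa.
* **Aerosols.** A smooth power-law extinction
  ($\mathring{a}=1.3$, scale height 2 km, AOT~550~ = 0.1 by default) with no
  structure at band scale; it creates the small out-of-band bias seen when
  only O~2~ is corrected.
* **Pressure with height.** The hydrostatic/ideal-gas closed form
  $p_{sen}=p\exp(-gM_0Z/R_0T)$. A widely reprinted version of this formula
  carries a positive exponent, which would make pressure grow with height;
  `strict_paper = TRUE` reproduces that sign for comparison.

## The synthetic scene

The default study conditions, fixed once: NIR reflectance plateau 0.5 with a
logistic red edge at 715 nm (effectively constant at band scale); SIF as two
Gaussians (687 nm, sd 10 nm; 741 nm, sd 25 nm) rescaled so
$F(760.6\,\mathrm{nm})=0.97$ mW m^-2^ sr^-1^ nm^-1^; a smooth 5800 K solar
baseline of ~1420 mW m^-2^ nm^-1^ at 760 nm (solar Fraunhofer lines are out
of scope — the retrieval windows exploit telluric O~2~ only); T = 288.15 K,
p = 1013.25 hPa, SZA 30°, VZA 0° (nadir), sensor heights 3-20 m. Everything
is deterministic given the configuration.

The seasonal analysis uses a sinusoidal annual meteorological series with the
temperature minimum at day-of-year 1 and maximum near day 180, peak-to-peak
swings of 40 K and 50 hPa (high-latitude boreal conditions, ~61°N), mean
277.15 K / 1000 hPa, and surface pressure anticorrelated with temperature
(winter-high). Surface pressure is mapped to the mid-path height before
evaluating the band model (a homogeneous-layer average; the correction is
<0.1% over 20 m). Day-to-day noise is available but off by default, since the
seasonal quantities of interest are cycle amplitudes.

## What the experiments show

```{r sweep, eval = FALSE}
tb <- run_sweep(sweep_spec(heights_m = c(3, 10, 20),
                           sensor_configs = list(c(0.1, 0.1), c(0.5, 1.0)),
                           setups = c(1, 2, 4), methods = "3fld"))
```

On the default conditions the toolkit reproduces the qualitative structure
of the proximal-sensing O~2~ problem: uncompensated retrievals (irradiance
and/or radiance taken at sensor level without correction) underestimate SIF
severely — beyond -50% even at 3 m — and the error grows monotonically with
sensor height; first-order compensation removes most of it, with a residual
that grows with spectral resolution width because of the convolution
inequality; the convolution-consistent scheme removes that residual too and
recovers SIF to within a few per cent at every resolution between 0.1 and
1 nm, limited only by the polynomial adequacy of the reflectance and
fluorescence models. The seasonal study shows that a 40 K / 50 hPa annual
cycle changes the 15-m O~2~-A band-minimum transmittance by ~0.01, enough to
imprint a spurious seasonal signal of a substantial fraction of the SIF level
on an uncompensated retrieval while the surface stays constant.

Problem sizes used throughout the scripted studies: the native grid is
0.005 nm over 749.5-777.5 nm (5601 points), five sensor heights, three to
four SR/SSI configurations, and 365-day seasonal series — small enough that
the full study suite runs in seconds while leaving the channelisation
operator oversampled by at least a factor of five at the finest resolution
studied.

## Numerical choices

* ISRF: Gaussian with FWHM = SR (the conventional spectrometer assumption;
  the shape is in principle instrument-specific), truncated at ±3 FWHM and
  renormalised (truncation error < 1e-4 of the kernel mass, and exactly
  renormalised away for constants); trapezoidal quadrature on the native
  grid; channel centres anchored so one centre falls exactly on 760.6 nm.
  If the kernel is narrower than one native step the nearest native sample
  is returned (the delta-ISRF limit).
* Band-depth and column calibrations solve for a single log-scale factor by
  root bracketing (tolerance well below the 1e-4 depth contract); the
  operation is idempotent to <1e-6 and cached per session.
* The atmosphere fit from at-sensor irradiance estimates one scalar (the
  column absorber scaling) by golden-section/parabolic minimisation of the
  channel residuals; on noise-free self-consistent input it recovers the
  truth to <0.1%, and results clipped at the search bounds or with rms
  residuals above 1e-3 are flagged.
* Degenerate inputs fail loudly: non-monotone wavelength grids, transmittance
  outside [0,1], zero-transmittance channels in a correction, FLD
  denominators within 1e-9 of zero, fitting windows with fewer channels than
  coefficients, and channel sets that exceed the native support of the
  spectrum being convolved.

## Limitations

* **Line widths.** The 0.005 nm native grid cannot resolve real O~2~ line
  cores, so the synthetic half-widths are ~10x physical. Band-scale depths,
  the existence and orderings of the convolution-inequality effects, their
  growth with path length and resolution width, and the seasonal band-depth
  response are all preserved; the *magnitudes* of within-channel structure
  at intermediate resolutions are smoother than over a real atmosphere
  (first-order compensation errors at SR ~0.4 nm come out smaller than
  field-scale studies report), while quantities that live on Lorentz wings
  where the column still transmits (e.g. the seasonal radiance excursion)
  come out larger. Passing tests therefore demonstrate the structure and
  internal consistency of the methods, not channel-exact agreement with any
  specific instrument over the real atmosphere.
* The short-path simplification drops path radiance, diffuse upward
  transmittance and adjacency; results do not extrapolate to airborne or
  satellite geometries.
* Measurements are treated as noise-free; no SNR model is included, so all
  reported errors are method biases, not precisions.
* Non-Gaussian or asymmetric ISRFs, spectral shift and stray light are out
  of scope; real spectrometers need their measured ISRF in place of the
  Gaussian assumption.
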