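---
title: "Simulating quenched chlorophyll fluorescence in a coupled atmosphere-ocean system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating quenched chlorophyll fluorescence in a coupled atmosphere-ocean system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorrt)
```

## The model

`fluorrt` simulates the solar-induced chlorophyll-a fluorescence signal seen
by sensors at the top of the atmosphere (TOA) and just beneath the sea
surface (TOO), with the fluorescence quantum yield responding to the
simulated underwater light field through photochemical and non-photochemical
quenching.

The radiance field obeys the plane-parallel scalar transfer equation

$$\mu\,\frac{dL}{dz} = -c\,L + S_{el} + S_C + S_R + S_Y,$$

where $c$ is the beam attenuation coefficient, $S_{el}$ the elastic
scattering source, and the inelastic terms are chlorophyll fluorescence
($S_C$), water Raman scattering ($S_R$) and dissolved organic matter
fluorescence ($S_Y$). The fluorescence source is isotropic,

$$S_C(z,\lambda) = \frac{1}{4\pi}\int b_C(z,\lambda,\lambda_e)\,
E_o(z,\lambda_e)\,d\lambda_e,\qquad
b_C = a_p\,\Phi_C\,\frac{1}{\sqrt{2\pi}\,\sigma_C}
e^{-(\lambda-\lambda_{C,0})^2/2\sigma_C^2}\,\frac{\lambda_e}{\lambda},$$

with a Gaussian emission line centered at $\lambda_{C,0}=685$ nm of width
$\sigma_C = 10.6$ nm, excited between 370 and 690 nm, and $a_p$ the
phytoplankton absorption coefficient. The quantum yield follows the
photo-compensation model

$$\Phi_C = q_I\,e^{-\mathrm{IPAR}/E_T}\left(\Phi_{C,min}\,
e^{-\mathrm{IPAR}/E_k} + \Phi_{C,max}\,(1 - e^{-\mathrm{IPAR}/E_k})\right),$$

where IPAR is the instantaneous photosynthetically available radiation, the
photon-flux integral of the scalar irradiance $E_o$ over the 370-690 nm
excitation window. The bracket describes photochemical quenching saturating
with scale $E_k$; the leading exponential describes non-photochemical
(energy-dependent) quenching that suppresses the yield under high light
with scale $E_T$; $q_I$ accounts for reaction-center quenching. Defaults
are $q_I = 0.35$, $\Phi_{C,min} = 0.03$, $\Phi_{C,max} = 0.09$,
$E_k = 55$ and $E_T = 634\ \mu\mathrm{mol\,quanta\,m^{-2}s^{-1}}$ —
representative of healthy open-ocean populations; all are scene parameters
because they vary substantially across species and physiological states.

Because the inelastic sources depend on the light field at the excitation
wavelengths, the simulation runs in two passes:

1. **Excitation pass.** The elastic problem is solved at every excitation
   wavelength (370-690 nm, 10 nm default spacing); $E_o(z,\lambda_e)$ is
   recorded at all water levels, then IPAR$(z)$ and $\Phi_C(z)$ follow.
2. **Emission pass.** At every emission wavelength (640-750 nm, 2.5 nm
   default), the volume sources are assembled from the stored excitation
   field and the transfer equation is solved again with the extra source.
   Superposition of the elastic and source-only solves yields the spectra
   and, on request, a per-mechanism decomposition.

Emission from the excitation-pass field is computed once; re-excitation of
inelastically scattered light is neglected (the Raman contribution to the
excitation-pass $E_o$ can be switched on with `raman_in_excitation`, and is
off by default so that the excitation pass is purely elastic).

## Optical properties

**Ocean.** Three components: pure sea water (packaged absorption table;
scattering $\propto\lambda^{-4.32}$ referenced to 0.00453 m$^{-1}$ at
450 nm), CDOM (exponential absorption with slope 0.018 nm$^{-1}$), and
chlorophyll-covariant particles. Particle absorption uses the packaged
$A(\lambda), E(\lambda)$ tables ($a_p = A\,[Chla]^{E}$, pigment packaging
included); particle beam attenuation uses the power law
$c_p = 0.39\,[Chla]^{0.57}(660/\lambda)$, a standard average relation for
chlorophyll-covariant particles; particle scattering is $c_p - a_p$
(clamped at zero with a warning under extreme overrides). The CDOM
amplitude is tied to the phytoplankton by $a_y(440) = 0.2\,a_p(440)$ unless
set explicitly — the spectral slope is well constrained by the literature
but the amplitude is scenario-specific, so a covarying default keeps the
scenario grid one-dimensional in [Chla]. The mixture phase function weights
a Rayleigh-like pure-water shape ($1 + 0.835\cos^2\theta$) and a
Henyey-Greenstein particle shape by the component scattering coefficients;
the particle asymmetry parameter is chosen so the phase function integrates
to the configured backscattering ratio (default 0.01, giving
$g \approx 0.95$).

**Atmosphere.** Rayleigh scattering from the standard column fit with
depolarization 0.0284, an 8 km molecular scale height, and a maritime-like
aerosol described by a Henyey-Greenstein phase function ($g = 0.75$, single
scattering albedo 0.98, Angstrom exponent 0.3, 2 km scale height) — an
analytic stand-in for a full Mie description of humidified sea-salt
aerosol. Gas absorption (oxygen B and A bands, water vapor, ozone
Chappuis) enters through a packaged band-averaged transmittance table at
1 nm resolution rather than line-by-line physics; the FLH anchor bands at
640/710/745 nm sit where the band model keeps column transmittance above
97%. The ILS convolution (`convolve_ils`, Gaussian, 5 nm FWHM default)
emulates a hyperspectral sensor's response.

## Solver numerics

The engine is a successive-order-of-scattering (SOS) code for the coupled
air-water stack:

- 32 Gauss nodes per hemisphere by default in the simulator. The particle
  phase function at backscattering ratio 0.01 is so strongly forward-peaked
  that delta-M truncation at 16 nodes leaves a ~7% error in the
  below-surface nadir radiance; a convergence scan showed the result
  settles to ~0.5% from 32 nodes on, so the simulator default is 32 while
  the lighter engine default (16) remains for property tests. Azimuth is
  handled by Fourier cosine modes; nadir viewing and all irradiances need
  only the azimuth-averaged mode.
- delta-M scaling per layer at $2N$ Legendre terms, with the first
  scattering order of the direct beams evaluated with the exact closed-form
  phase function (a TMS-style single-scattering correction).
- The direct beam is tracked analytically, refracted across the flat
  Fresnel interface with transmitted-flux weighting; the diffuse field is
  redistributed at the interface with flux-conserving transmission and
  reflection operators, including total internal reflection beyond the
  critical angle. The unscattered specular sun glint is a delta function in
  direction and is excluded from viewing radiances; its scattered orders
  are retained. The lower boundary is black.
- Layers: 10 atmospheric layers; 50 water layers refined exponentially
  toward the surface. The water domain spans three optical depths at the
  most transparent wavelength of the combined excitation+emission grid,
  clamped to 30-200 m. The rule is keyed to the excitation range rather
  than the emission range because IPAR must decay below the quenching
  saturation scale within the domain: in clear water the quantum-yield
  maximum sits at 60-100 m, far below where any emission wavelength still
  matters.
- Orders iterate until the order-$n$ contribution to the requested outputs
  falls below $10^{-4}$ (relative), with a cap of 100 orders and a warning
  carrying the residual if the cap is hit (the scenario suite grazes the
  cap only in the blue for the greenest water, at residuals within a
  factor of two of the tolerance).
- Viewing radiances come from integrating the converged source function
  along the exact line of sight, so nadir values do not depend on the
  quadrature node placement.

Verification is part of the test suite: first-order output against the
single-scattering closed form (the conservative $\tau = 0.01$ slab also
checks the full solution against an independently integrated second-order
term, which contributes +2.8% — single scattering alone is not the whole
answer even for thin conservative layers); flux conservation for
conservative columns; reciprocity; and an independent Monte-Carlo photon
oracle on a two-layer slab, agreeing within 3 standard errors at
$2\times10^6$ photons.

## What the scenarios emulate — and what they do not

The scenario generator reproduces the study conditions: [Chla] in
{0, 0.03, 0.1, 1, 10} mg m$^{-3}$, aerosol optical depths {0, 0.1, 0.2,
0.5}, solar zeniths {0, 30, 60, 78}$^\circ$, nadir viewing, vertically
homogeneous water. The packaged solar spectrum is a smoothed
(Fraunhofer-line-free) extraterrestrial irradiance at the standard absolute
scale; fixture tables are smooth synthetic reconstructions of the
literature curves. Passing tests therefore demonstrate the model's internal
physics (transport, quenching response, spectral behavior, orderings), not
agreement with any particular field dataset: real waters have
depth-structured chlorophyll, spectrally structured solar irradiance,
wind-roughened surfaces and polarization, all outside this model's scope.
Reflectance scales at red wavelengths are sensitive to the particle
extinction and backscattering-ratio constants, which are average relations
here; relative and qualitative quantities (peak positions, orderings,
profile shapes) are much more robust than absolute reflectances.

## Degenerate inputs and tie-breaks

Zero chlorophyll zeroes the fluorescence source exactly (and the default
CDOM tie); zero aerosol leaves a pure Rayleigh atmosphere; a zero-thickness
layer transports radiance unchanged. The excitation window is treated
inclusively at its endpoints so that quadrature on a grid touching 370 or
690 nm integrates the same function as a dense grid. FDOM is disabled by
default (no efficiency value is well constrained); enabling it requires an
explicit `fdom_eta`, with a Stokes-shifted Gaussian emission kernel so the
emitted power never exceeds the absorbed power times the efficiency.

## Known limitations

- Scalar (intensity-only) transport; polarization alters visible TOA
  reflectances at the few-percent level and is out of scope.
- Band-model gas absorption: adequate for band-integrated reflectances and
  the FLH bands, not for resolving line cores.
- Flat interface; no bottom reflectance; homogeneous pigment profile.
- The absolute underwater light level (hence IPAR and the quenching state)
  inherits the simplified atmosphere and the smooth solar spectrum; the
  quenching exponentials make some sensitivity metrics strongly dependent
  on that absolute scale.

## Problem sizes

The default run solves 33 excitation and 45 emission wavelengths with 32
streams per hemisphere over 60 layers; one scenario takes tens of seconds
on a single core, and the full sensitivity suite (nine scenarios) a few
minutes. These sizes were chosen so that refining any of them changes the
headline outputs by well under 1%.
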