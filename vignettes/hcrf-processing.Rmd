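---
title: "Processing field spectro-goniometer sessions into HCRF hemispheres"
author: "goniohcrf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing field spectro-goniometer sessions into HCRF hemispheres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goniohcrf)
```

## The measurement and its model

A dual-beam field spectro-goniometer samples the radiance reflected by a
vegetated target plot from up to 61 view directions on a spherical shell
(view zenith up to 30°, full azimuth circle) while a second radiometer with
a cosine foreoptic records the down-welling irradiance continuously. The
natural illumination is hemispherical and the sensor has a finite opening
angle (IFOV 8.5°), so the measured quantity is the *hemispherical conical
reflectance factor* (HCRF) — the field-practical stand-in for the
bidirectional reflectance factor (BRF), which itself approximates
π·BRDF under isotropic-irradiance assumptions.

Per wavelength λ and view direction $(\theta_r, \phi_r)$ the package
computes

$$\mathrm{HCRF}(\lambda;\theta_r,\phi_r) =
  \frac{L_r(\lambda; t_x)}
       {L_{ref}(\lambda; t_0)\; c_{diff}(\lambda; t_x)\;
        c_{ref}(\lambda, \theta_i)}$$

with

* $L_r$ — target radiance at its acquisition time $t_x$;
* $L_{ref}$ — Spectralon reference-panel radiance, measured at nadir at
  the session start $t_0$ (and again at the end, for consistency checking);
* $c_{diff}(\lambda;t_x) = E(\lambda,t_x)/E(\lambda,t_0)$ — the
  irradiance drift weight that interpolates the panel measurement to the
  target's timestamp, using the continuous irradiance record of the second
  radiometer;
* $c_{ref}(\lambda,\theta_i)$ — the panel correction factor accounting
  for the panel's calibrated reflectance and its non-Lambertian response to
  the sun zenith angle $\theta_i$.

Two assumptions underlie the reduction: irradiance changes affect the
panel radiance proportionally in each wavelength region (so the ratio
$c_{diff}$ transfers), and target and panel share the same illumination.
Values above 1 are legitimate (backscatter brightening) and are never
clipped.

Derived quantities:

* **ANIF** (anisotropy factor): HCRF normalized by the nadir HCRF per
  wavelength — 1 at nadir by construction, isolating the angular signature
  from the spectral one.
* **ANIX** (anisotropy index): per wavelength, max/min HCRF over an
  azimuth plane (nadir belongs to every plane); reported for the solar
  principal plane (where canopy anisotropy is strongest) and the
  orthogonal plane, with means over the visible (400–700 nm) and NIR
  (700–1050 nm, grid-limited) regions.
* **Angular NDVI**: band-averaged HCRF in red (672 ± 5 nm) and NIR
  (864 ± 5 nm) windows per view position, plus the nadir-normalized
  surface. These band centres are the conventional plotting wavelengths
  for spectro-directional vegetation data; both are configurable.

### The panel correction convention

The calibration object stores the per-wavelength panel factor `rref` and an
optional correction grid `cref(λ, θ_i)`; with no grid the correction
degenerates to `rref`. Because $c_{ref}$ sits in the denominator, it is the
factor that maps the *measured* panel radiance to its ideal-Lambertian
equivalent $E/\pi$ — equivalently, the panel's physical BRF under this
convention is $1/c_{ref}$. The synthetic session generator uses exactly
this convention, which makes pipeline recovery an algebraic identity on
noiseless input. Published panel-anisotropy coefficients are not shipped;
`syntheticPanelCalibration()` provides a physically plausible synthetic
table (gentle falloff of the effective panel reflectance with sun zenith)
clearly labelled as such, and any user-supplied grid plugs into the same
slot.

### Estimating the drift weight

$c_{diff}$ is defined pointwise from two irradiance samples, and
`cDiff(..., method = "nearest")` implements exactly that (nearest sample
within 5 s, linear interpolation in time as fallback). The processing
chain, however, defaults to `method = "smooth"`: a per-wavelength local
linear fit through the 7 samples nearest each lookup time. The reason is
statistical: each irradiance spectrum carries the same multiplicative
sensor noise as the radiance channels (~0.5%), and a two-sample ratio
injects √2 times that noise into every HCRF — more than the bias a 1%
session drift creates in the first place. The local fit exploits the full
63-sample record; it is exact for noiseless linear drift (so all algebraic
identities are preserved), unbiased under locally linear drift, and
averages the noise down by roughly √7. For step-like events the fit smears
the transition over half a window (~±1.5 min at the default 24 s cadence);
the `"nearest"` method localizes steps sharply and remains available
per-call and through `processSession(driftMethod = )`.

### Drift indicator and session score

The audit trail for interpretation: per view position, the broadband mean
of $|c_{diff}(t_x) - 1|$ measures how much panel interpolation that
position needed; positions above 2% (configurable) have their quality flag
suffixed `+caution`. The session-level consistency score propagates the
start panel to the session end ($L_{ref}(t_0)\,c_{diff}(t_{end})$) and
reports the broadband relative mismatch with the measured end panel — 0
when the real drift was purely multiplicative and spectrally uniform, and
`NA` (flagged) when the end panel is missing. The exact formula of the
original instrument's indicator was never published; this construction is
the package's own, chosen to be 0 in the ideal case and monotone in the
amount of interpolation performed.

## Geometry

* **Measurement scheme.** Nadir + a 5° ring with 12 azimuths + 10°/20°/30°
  rings with 16 azimuths each (61 positions). Only the counts and the
  qualitative rule "denser around the solar principal plane" are
  documented for the original instrument, so the azimuth layout here is the
  package's own: symmetric half-layouts {0, 25, 55, 90, 125, 155, 180}°
  (12-ring) and {0, 15, 35, 60, 90, 120, 145, 165, 180}° (16-rings),
  mirrored about the principal plane. Every ring contains the principal
  (0°/180°) and orthogonal (90°/270°) planes — the constraint the ANIX
  planes rely on — and spacing tightens toward the principal plane. Both
  layouts are arguments of `defaultScheme()`.
* **View azimuth convention.** Principal-plane referenced, 0° = backward
  scattering (sensor on the sun's side of the target). Polar plots put the
  backward half up and the sun at the bottom.
* **Solar ephemeris.** A NOAA/Meeus-style algorithm (apparent declination
  and equation of time from the Julian century; geometric zenith, no
  refraction), accurate to a few hundredths of a degree — an order of
  magnitude inside the 0.1° requirement and two orders inside the 1°
  reporting precision. The test suite cross-checks 1000 random
  (site, time) draws against an independently implemented Astronomical
  Almanac algorithm.
* **Principal-plane correction.** The sun's azimuth moves ~8° during a
  25-minute Arctic noon session; `principalPlaneCorrection()` returns, per
  ring, the azimuth offset to dial in before rotating the arc (solar
  azimuth at ring start minus at session start), keeping the projected
  principal plane aligned.
* **Footprint.** Edge-ray construction of the sensor cone on the ground
  plane (sensor on the arc at a constant 2.02 m slant distance). At nadir
  the footprint is a 30.0 cm circle; at the 30° position the major extent
  reaches 34.7 cm. The cross-track width and ellipse area come from a
  dense sampling of the cone boundary (2000 rays — exact to well below a
  millimetre); the instrument's published extents are reproduced within
  0.1 cm.
* **Hot spot.** Feasible only when the minimum sun zenith is within the
  view-zenith range. A one-year ephemeris sweep at the Arctic circle gives
  a minimum solar zenith of ≈43.1° (latitude minus obliquity), so with a
  30° maximum view zenith the hot spot cannot occur at Arctic sites.

## The synthetic session generator

`simulateSession()` stands in for the instrument: it emits, in acquisition
order with timestamps, the start panel, 61 targets, the end panel, and one
irradiance spectrum per radiance acquisition (126 spectra in total), in
exactly the ASCII dialect and manifest format the reader consumes, with
the exact BRF on the nominal scheme grid recorded as ground truth.

What it emulates, with defaults chosen as the conditions a field session
of this instrument class would see:

| parameter | default | rationale |
|---|---|---|
| base spectrum | `vegetationSpectrum()` | chlorophyll wells, red edge, NIR plateau ≈0.5 |
| angular kernel | `1 + x(k_b\cos\phi_r + k_a)`, `x = θ_r/30` | smooth backscatter/bowl shape; vis `k_b`=0.35, `k_a`=0.05 → principal-plane ANIF ≈1.45 backward / 0.75 forward at 30°; NIR `k_b`=0.10 → ≈1.1/0.9; anisotropy stronger in the visible, as observed for low canopies |
| irradiance drift | +0.2%/min (≈5% per session), optional step events | clear-sky drift magnitude; steps emulate passing atmospheric changes |
| sensor noise | 0.5% multiplicative, per wavelength | brackets the radiometer's 0.20–1.59% reflectance uncertainty |
| pointing jitter | sd 3 cm on the ground | the instrument's characterized deviation stays within ±6 cm |
| PP misalignment | sd 1.75° per session | compass-setting uncertainty 1.5–2° |
| cadence | 24 s | 61 targets + end panel ≈ 25 min, the documented session length |

The angular kernel is a *test fixture*, not a canopy model: it reproduces
the qualitative field pattern with a known closed form so that recovery
can be asserted exactly. Features of real data the generator does not
emulate: diffuse/direct illumination partition (target and panel share one
irradiance, as the reduction assumes), wind-driven canopy movement,
spectrally structured drift, and sensor dark-current drift. Passing tests
therefore demonstrate the correctness of the reduction algebra and its
noise behaviour, not radiative realism.

`conicalAverage()` quantifies the conical-vs-directional approximation by
Monte-Carlo averaging a directional reflectance function over the 8.5°
sensor cone (uniform in solid angle).

## Numerical and screening choices

* **Quality screening.** Noise test: median absolute second difference of
  a spectrum relative to its median level; the default threshold 0.05 is
  calibrated on the generator's clean output at the instrument's 1.5 nm
  sampling (clean canopy spectra stay below ~2% even with 0.5% sensor
  noise, alternating artifacts reach ~40%). Outlier test: broadband level
  versus the ring median, flagged beyond 5×MAD; rings with fewer than 3
  testable members are `untestable` (the nadir singleton always is). A
  spectrum failing the noise test keeps its `noisy` flag rather than being
  re-labelled `outlier`. Both thresholds are engineering defaults — the
  original instrument's statistics were never published — and are
  config-overridable.
* **Wavelength alignment.** Calibration tables are linearly interpolated
  onto the spectrum grid (negligible at 1.5 nm sampling); spectra entering
  a ratio must share a grid exactly — no silent resampling.
* **Timestamps.** Stored with explicit UTC offset, all ephemeris
  computation in UTC.
* **No smoothing of spectra before ratios**; the only smoothing anywhere
  is the (documented, optional) drift-weight estimator above.
* **Plot interpolation** (bilinear in zenith/azimuth, circular per ring,
  exact at the scheme nodes) is presentation-only; every statistic is
  computed on the raw scheme nodes.

## Problem sizes in the test suite

The property tests run full 61-position sessions on a 31-point wavelength
grid — the angular structure is what the properties exercise, and every
reduction step is per-wavelength independent, so a coarse spectral grid
loses no generality. Tests of the quality screen use the full 467-point
instrument grid (1.5 nm), because the noise statistic's threshold is
calibrated for that sampling. The ephemeris cross-check draws 1000 random
site/time pairs; the hot-spot sweep covers one year at 20-minute
resolution in tests and 5-minute resolution in the acceptance script.

## Known limitations

* HCRF is the terminal quantity: no HDRF/BRDF conversion under
  diffuse-light decomposition, and no BRDF model inversion.
* The shipped panel-anisotropy table is synthetic; quantitative work needs
  the panel's factory calibration loaded into `PanelCalibration()`.
* The scheme's azimuth layout is a documented convention, not a
  reconstruction of the original engraved module.
* The session-start solar azimuth of the bundled Arctic case study
  evaluates to ≈176° rather than the nominal due-south 180°; the session
  simply began ~12 minutes before true solar noon.
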