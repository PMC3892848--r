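# goniohcrf

Processing of dual-beam field spectro-goniometer sessions into
hemispherical conical reflectance factors (HCRF) and reflectance-anisotropy
products, for spectro-directional remote sensing of low vegetation canopies.

A field spectro-goniometer samples the radiance reflected by a target plot
from many view directions (here: 61 positions within a 30° zenith cone)
while a second radiometer records the down-welling irradiance continuously.
Under natural hemispherical illumination with a finite sensor opening angle,
the measurable reflectance quantity is the HCRF. This package implements the
full reduction for such sessions, the instrument geometry around it, a
synthetic session generator with known ground truth, hemisphere plots, and
a command-line interface.

## The core reduction

Per wavelength λ and view direction (θ_r, φ_r):

    HCRF(λ; θ_r, φ_r) = L_r(λ; t_x) / ( L_ref(λ; t_0) · c_diff(λ; t_x) · c_ref(λ, θ_i) )

where `L_r` is the target radiance at time `t_x`, `L_ref` the nadir
Spectralon panel radiance at session start `t_0`,
`c_diff = E(λ,t_x)/E(λ,t_0)` the irradiance drift weight that interpolates
the panel measurement in time, and `c_ref` the panel's anisotropy
correction against sun zenith θ_i. Derived products: the anisotropy factor
ANIF = HCRF/HCRF_nadir, the anisotropy index ANIX = max/min HCRF over an
azimuth plane per wavelength, and angular (nadir-normalized) NDVI surfaces.
Geometry utilities cover the 61-position measurement scheme, a solar
ephemeris (≤0.1° accuracy), per-ring principal-plane correction offsets,
ground-footprint ellipses of the 8.5° sensor cone, and hot-spot
feasibility. See the methods vignette (`vignettes/hcrf-processing.Rmd`)
for the model, conventions and design choices.

## Worked example

Simulate a full session (anisotropic vegetation scene, 5 %/session
irradiance drift, 0.5 % sensor noise, pointing jitter) and process it:

```r
library(goniohcrf)

scene <- SceneModel()                      # vegetation-like BRF ground truth
acq   <- AcquisitionModel(seed = 7)        # instrument/illumination error model
ses   <- simulateSession(scene, acq)       # 61 target + 2 panel + 63 irradiance
hem   <- processSession(ses, panel = acq@panel)
hem
#> HemisphereDataset: 61 positions x 467 wavelengths
#>   sun zenith 47.5 deg, azimuth 176.2 deg; flags: ok=23 ok+caution=37 untestable=1
#>   session drift-consistency score: 0.006549

anix(hem, c(0, 180), label = "principal")
#> AnisotropySummary plane principal: 9 positions, ANIX 1.195-2.006 (vis mean 1.956, nir mean 1.254)
anix(hem, c(90, 270), label = "orthogonal")
#> AnisotropySummary plane orthogonal: 9 positions, ANIX 1.008-1.087 (vis mean 1.063, nir mean 1.024)
```

Anisotropy is pronounced in the solar principal plane and weak in the
orthogonal plane, and stronger in the visible (mean ANIX 1.96) than in the
NIR (1.25) — the canopy-shadowing pattern the instrument was built to
measure. The `+caution` flags mark positions whose drift indicator exceeded
2 % (the later rings, where more panel interpolation was needed); the
session score ≈0.007 is the broadband start/end panel consistency mismatch,
here purely sensor noise. Recovery against the simulator's exact truth:

```r
truth <- groundTruth(ses)$brf
sqrt(mean(((hcrfValues(hem) - truth) / truth)^2))
#> truth-relative RMS error of recovered HCRF: 1.23%
```

The angular NDVI surface tilts along the principal plane — lower backward,
higher forward than at nadir:

```r
subset(viAngular(hem), zenith == 30 & azimuth %in% c(0, 180))
#>      id zenith azimuth      ndvi  ndviNorm
#> P46 P46     30       0 0.7938529 0.9542326
#> P54 P54     30     180 0.8661172 1.0410962
```

Geometry checks against the instrument characterization:

```r
footprint(30)                # 2.02 m slant distance, 8.5 deg IFOV
#> FootprintEllipse: major 34.7 cm, minor 30.1 cm, area 820 cm2, center offset -0.7 cm
solarPosition(69.6744, -148.7208, "2012-07-09T13:48:00-08:00")
#>     zenith  azimuth
#> 1 47.49259 176.1575
```

Plots: `plotHemisphere2D()` (polar hemisphere, principal plane vertical,
sun at the bottom), `plotPPTransect()`, `plotHemisphere3D()`.

## Command line

```sh
Rscript inst/scripts/goniohcrf simulate --out session_dir --seed 3
Rscript inst/scripts/goniohcrf process  --config run.yml --out results_dir
Rscript inst/scripts/goniohcrf scheme   --out scheme_dir
```

`process` writes the hemisphere table, an NDVI table, a report (flags,
per-plane ANIX, session drift score) and the plots, with every stage
appended to a timestamped log; the effective configuration is recorded in
the output directory.

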