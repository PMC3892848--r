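Package: goniohcrf
Title: Processing of Field Spectro-Goniometer HCRF Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ground-based spectro-directional remote sensing of
    vegetation canopies with a dual-beam field spectro-goniometer. Reads raw
    session spectra (digital numbers, radiance, irradiance) with their
    calibration tables and manifests, converts and quality-screens them, and
    derives hemispherical conical reflectance factors (HCRF) with
    reference-panel anisotropy correction and continuous-irradiance drift
    weighting. Computes anisotropy factors (ANIF) and indices (ANIX), angular
    vegetation-index surfaces, instrument geometry (measurement schemes, solar
    ephemeris, principal-plane correction, footprint ellipses, hot-spot
    feasibility), and polar-hemisphere visualizations. Includes a synthetic
    session generator with known ground-truth reflectance for end-to-end
    verification, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
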