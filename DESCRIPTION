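Package: fluorrt
Title: Coupled Atmosphere-Ocean Radiative Transfer with Chlorophyll
    Fluorescence Quenching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scalar successive-order-of-scattering radiative transfer for a
    plane-parallel atmosphere coupled to a homogeneous ocean through a flat
    Fresnel interface, with inelastic in-water sources: chlorophyll-a
    fluorescence whose quantum yield responds to the simulated instantaneous
    photosynthetically available radiation through a photochemical and
    non-photochemical quenching model, plus simplified water Raman scattering
    and dissolved organic matter fluorescence. Includes spectral bio-optical
    and atmospheric optical property models, a two-pass simulator producing
    top-of-atmosphere and top-of-ocean reflectance spectra with optional
    Gaussian instrument line shape convolution, and a hyperspectral
    fluorescence line height toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
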