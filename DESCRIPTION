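Package: lsmtools
Title: Design, Simulation, Calibration and Reconstruction Toolkit for
    Light-Sheet Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A computation stack for home-built light-sheet microscopes
    (LSM/SPIM). Provides closed-form optical design calculators for
    Gaussian, Bessel and Airy illumination beams, sheet dimensions
    through a lens train, objective resolution, sampling and depth of
    field; a synthetic acquisition simulator (bead phantoms and
    Brownian-diffusion movies rendered through a tilted sheet with
    per-slice skew and camera noise); calibration procedures for pixel
    size, axial skew, sheet angle and sheet dimensions; a static
    reconstruction pipeline (de-skew, Richardson-Lucy 3D deconvolution,
    local background thresholding, volume assembly, line sections); and
    an fcsSOFI dynamics engine combining pixel-wise fluorescence
    correlation spectroscopy with second-order cross-correlation SOFI
    imaging and hue/saturation fusion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tiff,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'optics.R'
    'simulate.R'
    'calibrate.R'
    'reconstruct.R'
    'dynamics.R'
    'io.R'
    'cli.R'
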