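Package: spimdiff
Title: Vascular Permeability Quantification from Light-Sheet Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies dye extravasation and effective diffusion from
    selective-plane-illumination (SPIM) time-lapse stacks. Extracts mean
    fluorescence intensity traces at graded distances from a vascular or
    injection source, fits a delayed point-source Fickian diffusion model
    globally across traces with a shared diffusion coefficient, and performs
    an independent half-time wavefront analysis (wave speed, polynomial
    corrected diffusion estimate, and grid-matched injection-to-observation
    delay). Includes a synthetic SPIM-stack and trace generator with presets
    for agarose point-injection calibrations, control zebrafish embryos and
    tumour-xenograft embryos, plus optics quality control (light-sheet
    thickness and lateral PSF from calibration images).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    tiff,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
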