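Package: sirtdose
Title: Voxel-Based Patient Dosimetry for Yttrium-90 Radioembolization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three-dimensional absorbed dose distributions for
    yttrium-90 selective internal radiation treatment (SIRT) from
    quantitative 90Y PET imaging. Provides phantom-based scanner
    sensitivity calibration, voxel S-value kernel handling with
    energy-conserving resampling, dose-rate convolution and integration
    of the decaying dose rate for a permanent implant, dose-volume
    histograms, linear-quadratic radiobiology (biologically effective
    dose, EQD2 at 2 Gy per fraction, Poisson tumor control probability),
    the classical two-compartment partition model, and a synthetic
    phantom and virtual-patient generator so the whole pipeline can be
    exercised without clinical data. Reads and writes NIfTI and a
    minimal DICOM subset including RT Dose.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
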