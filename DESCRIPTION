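Package: frexpan
Title: Simulation and Analysis of Polarization-Modulated Fluorescence
    Microscopy with Excitation Polarization Angle Narrowing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and analysis of fluorescence polarization
    microscopy (FPM) acquisitions in which the excitation polarization is
    rotated continuously, including the frame-separated excitation
    polarization angle narrowing (FrExPAN) pulse scheme for negatively
    switching fluorescent proteins.  Provides a synthetic-data generator
    (membrane geometries, anchored transition-dipole fields, cos-squared
    excitation, photoswitching doses, a Poisson/read-noise camera model),
    the raw-data processing chain (per-pixel stack mean normalization,
    switch/readout frame demultiplexing, periodic averaging, per-pixel FFT
    demodulation and phase-coded rendering), ExPAN-factor model fitting
    with automated ROI selection and group statistics, and three
    deconvolution paths: per-frame Richardson-Lucy, a penalized
    space-by-phase deconvolution of SPoD data, and a per-pixel
    three-parameter local polarization amplitude (ALPA) model fitted
    through a PSF-blur forward model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    grDevices,
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
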