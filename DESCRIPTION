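Package: confinedfcs
Title: In Silico Fluorescence Correlation Spectroscopy in Confined Bacterial Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates fluorescence correlation spectroscopy (FCS) experiments
    on point emitters diffusing inside a spherocylindrical (capsule-shaped)
    bacterial cell observed through a 3D Gaussian confocal volume, for both
    Brownian and fractional Brownian (subdiffusive) motion. Computes intensity
    autocorrelation functions on logarithmic lag grids with photobleaching
    detrending and a chromophore-blinking multiplier, and fits them with
    anomalous-diffusion and Ornstein-Uhlenbeck confined-diffusion models by
    Levenberg-Marquardt least squares. Includes downstream analyses of protein
    mobility: inverse power-law scaling of diffusion coefficients with
    molecular mass, Stokes-Einstein and linked two-bead (dumbbell) reference
    models, and buoyant-density estimation from exponential sedimentation
    profiles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
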