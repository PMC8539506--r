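Package: icefront
Title: Infrared Thermography Analysis of Vial Freezing in Freeze-Drying
Version: 0.1.0
Authors@R:
    person("Icefront", "Developers", email = "icefront@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the freezing stage of vial freeze-drying
    (lyophilization) with infrared thermography and SEM image analysis. A
    one-dimensional enthalpy-marching freezing simulator and a thermal-stack
    renderer provide physically structured synthetic camera data with known
    ground truth. Processing routines extract per-line axial temperature
    profiles, apply a graybody emissivity correction, locate per-line
    extrema (Tmin/Tmax and their heights) and average them line to vial to
    batch. Front-analysis routines turn extrema traces into freezing-front
    trajectories, frozen-layer temperature gradients, freezing intervals
    and gradient-inversion labels. A multivariate-image-analysis (MIA)
    pipeline segments pores in SEM cake images (brightness equalization,
    moving-window texture matrix, PCA score thresholding, Canny edges,
    dimensional filter) and pore-size statistics compare dispersion
    (variance, interquartile range) across experimental groups against a
    scaled beta distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
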