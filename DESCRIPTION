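Package: baroptics
Title: Barents Sea Bio-Optical Model Linking Glider and Satellite Ocean-Colour Observations
Version: 0.1.0
Authors@R:
    person("Barents", "Optics Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward bio-optical model for the Barents Sea that converts
    standard glider sensor outputs (salinity, chlorophyll fluorescence,
    particulate backscattering at 700 nm) into spectral bulk inherent
    optical properties (absorption, scattering, backscattering) and
    remote-sensing reflectance. Includes despiking and profile
    segmentation of glider sawtooth time series, a hybrid
    fluorescence/backscattering chlorophyll estimator that mitigates
    surface fluorescence quenching, Barnes objective-analysis gridding of
    transects onto a 2 km x 5 m raster, a simplified reflectance model
    for comparison with satellite ocean-colour ensembles, and a
    synthetic-data generator emulating a south-to-north transect across
    the polar front.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
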