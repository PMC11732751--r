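Package: equaflux
Title: Turbulent Nitrate Flux and Seasonal Mixing Climatologies for the
    Equatorial Ocean
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for upper-ocean turbulence and nutrient supply
    at the equator: dissipation-rate estimation from microstructure shear via
    Nasmyth-spectrum band integration, Osborn diapycnal diffusivity and upward
    diffusive nitrate flux, Equatorial Undercurrent core detection and
    core-relative composites, Richardson-number fields, and seasonal
    climatologies (mooring composites and Gaussian-distance-weighted profile
    regressions) with effective-sample-size uncertainty propagation. Includes
    a synthetic-data generator that emulates cruise sections, microstructure
    shear records, mooring time series and profile clouds with known ground
    truth, so every stage of the pipeline is verifiable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
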