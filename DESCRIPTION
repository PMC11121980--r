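Package: mothtrack
Title: Wind-Borne Moth Migration Trajectories and Light-Trap Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for nocturnal insect migration studies that
    combine searchlight-trap monitoring with atmospheric trajectory
    simulation. Provides a gridded wind/temperature data model with
    CF-style NetCDF input and output, quadrilinear field sampling, a NOAA
    solar ephemeris for deriving nightly flight windows (take-off shortly
    after sunset, landing shortly before the next sunrise), a biologically
    gated Lagrangian trajectory integrator over fixed flight altitudes
    (forward runs locate landing areas, backward runs locate source
    areas), point-in-polygon attribution of trajectory endpoints to named
    regions with seasonal percentage tables, and trap-catch phenology
    statistics: monthly summaries, the 1:1 sex-ratio chi-square, Fisher
    optimal partitioning of ordered samples for migration-period
    segmentation, and ovarian development / mating summaries. Synthetic
    atmosphere and trap-catch generators make every stage testable without
    proprietary meteorology or raw trap data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    sp
Config/testthat/edition: 3
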