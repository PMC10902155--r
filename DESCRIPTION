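Package: rhinocomp
Title: Comparing Nasal Airway Geometries Under Constant Flow, Pressure, or Power Forcing
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing two airway geometries (for example a pre-operative
    anatomy and its virtual-surgery counterpart) under the three global forcing
    strategies used in computational studies of nasal airflow: constant flow rate
    (CFR), constant pressure gradient (CPG) and constant power input (CPI).
    Provides the forcing controllers and global-quantity bookkeeping, a quasi-steady
    lumped-parameter airway network with closed-form oracles, a two-dimensional
    incompressible duct solver (projection method on a staggered grid) as a
    desk-scale dynamical stand-in for anatomical simulations, a comparison engine
    producing tabulated pre/post reports with nasal resistance, a synthetic
    pre/post case generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
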