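Package: tsmode
Title: Graph-Based Internal-Coordinate Characterization of Transition-State Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Perceives chemically valid molecular graphs (connectivity, bond
    orders, formal charges) directly from Cartesian XYZ coordinates, including
    nonequilibrium transition-state geometries, and translates an imaginary
    normal mode or an IRC/QRC trajectory into bond, angle and dihedral changes.
    The screened internal-coordinate changes are classified into bond
    formation/cleavage, hindered rotation and pyramidal inversion without prior
    knowledge of reactant or product structures, and emitted as a structured,
    machine-readable report suitable for high-throughput transition-state
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
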