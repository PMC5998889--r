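Package: regushift
Title: Transition Analysis of Gene-Regulation Activity in Time-Course
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects when gene regulations switch on and off along a
    time-course expression profile. Given a regulation-intensity matrix
    (computed internally from an expression profile and a directed gene
    regulatory network, or imported from an external tool), the package
    finds the partition of the time axis into periods, together with a
    binary active/inactive state for every regulated gene in every
    period, that maximizes a BIC-penalized activity score. Both an
    exhaustive search and an equivalent dynamic program are provided,
    along with seeded synthetic-data generators with planted period
    structure, period-activity reports, and score-versus-period tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
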