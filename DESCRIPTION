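Package: osmoforge
Title: SeDeM Powder Scoring, Factorial Optimization, Dissolution Kinetics and
    PK Simulation for Osmotic Tablet Development
Version: 0.1.0
Authors@R:
    person("Osmoforge", "Developers", email = "osmoforge@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for the computational side of osmotic
    controlled-release tablet development. Converts raw powder micromeritic
    measurements into SeDeM expert-system radius profiles and compressibility
    indices with corrective-excipient planning; builds and analyses two-level
    full factorial designs with Derringer-Suich desirability optimization;
    fits the seven classical dissolution-kinetics models (zero order, first
    order, Higuchi, Korsmeyer-Peppas, Hixson-Crowell, Baker-Lonsdale,
    Weibull) and compares release profiles with the f2 similarity factor;
    and simulates plasma concentration-time profiles from in vitro release
    data through a compartmental absorption-and-transit model coupled to
    two-compartment disposition, with non-compartmental analysis and
    dose-normalized relative bioavailability. A synthetic-data module
    generates every input with known ground truth so the whole pipeline is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
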