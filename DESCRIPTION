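Package: rgcskit
Title: Thermodynamics and Yield Accounting for Cell-Free Glycine Synthesis
    Cascades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for chemoenzymatic CO2-to-amino-acid cascades
    built on the reversible glycine cleavage system (rGCS). Provides
    transformed Gibbs-energy arithmetic (concentration and ionic-strength
    adjustment, Hess-law step substitution, flux-force forward/reverse flux
    fractions), a catalog of candidate glycine-synthesis pathways with
    step-wise thermodynamic profiling, initial-rate estimation from HPLC
    time courses, carbon-yield and titer accounting, direct-air-capture
    bookkeeping with closed-system carbonate speciation, 13C SIM fragment
    mass-shift modelling with enrichment inversion, and seeded synthetic-data
    generators for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
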