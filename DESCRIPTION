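Package: fruitflux
Title: Constraint-Based Flux Analysis of Developing Fruit from Metabolite Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate metabolic fluxes in developing fruit pulp from
    metabolite and biomass time courses. Concentration data are converted to a
    per-fruit basis, fitted with low-order polynomials and differentiated to
    obtain net accumulation fluxes, which constrain a non-compartmented
    stoichiometric model of central carbon and polyphenol metabolism. At each
    developmental stage the flux distribution is computed as the minimum-norm
    solution of a strictly convex quadratic program under pseudo-steady-state,
    reversibility and boundary constraints. Includes a curated plantain
    (Musa) central-metabolism network, a synthetic-study generator with known
    ground truth for validation, and downstream statistics (metabolite ratio
    summaries, Pearson correlation screens with false-discovery-rate control,
    and two-way ANOVA with Fisher LSD letter displays).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown,
    pracma
Config/testthat/edition: 3
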