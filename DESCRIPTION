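Package: sbmsaxs
Title: Structure-Based-Model Dynamics with SAXS-Driven Ensemble Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for determining solution ensembles of multidomain proteins
    by combining all-atom structure-based (Go-like) molecular dynamics with
    small-angle X-ray scattering. Builds shadow-map topologies from native
    coordinates, runs Langevin dynamics on the structure-based potential,
    computes theoretical scattering profiles by the Debye formula, scores
    conformations against experimental curves with scale-optimized chi-square,
    selects representative ensembles by a chi-square band plus projection
    point-density rule, and performs the accompanying shape (P(r), Dmax,
    Guinier) and spectroscopy analyses: 19F relaxation exponential fits,
    amide-I Voigt band deconvolution with secondary-structure fractions, and
    dynamic light scattering cumulant analysis. Includes seeded synthetic-data
    generators with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    bio3d,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
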