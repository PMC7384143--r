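Package: leafprod
Title: Community Leaf Size, Climate and Ecosystem Primary Productivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the macroecological inference chain linking species
    leaf-size compilations and range data to gridded community mean leaf
    size, trait-climate models, and inverse-logistic transfer functions
    that predict ecosystem gross and net primary productivity. Includes a
    synthetic data generator (spatially autocorrelated climate fields,
    trait-coupled species niches, presence/absence ranges, birth-death
    phylogenies with tunable trait signal), 50-km gridding utilities,
    candidate regression families, Dutilleul's modified t-test with
    effective sample size, hierarchical and commonality partitioning of
    R-squared, Blomberg's K with permutation tests, piecewise structural
    equation models, and cross-region validation of transfer functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
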