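Package: gibbspop
Title: Household-Level Synthetic Populations by Gibbs Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates household-level synthetic populations by Markov chain
    Monte Carlo (Gibbs) sampling over an explicit conditional-probability
    tree estimated from census-style microdata, with hierarchical spatial
    fallback for sparse cells. Individuals are co-generated within their
    household under structural constraints (roles by position, spouse gender
    complement, head minimum age, mother-child age gap), then enriched with
    income (socio-professional-category weighting of commune median incomes
    with statutory floors) and overweight/obesity attributes. Dwellings are
    derived from building geometry and households are allocated to dwellings
    by matching income strata to price classes. Validation compares marginal
    and multi-attribute joint distributions with SRMSE, R-squared, RMSE and
    MAE at regional and sub-zonal scales.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
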