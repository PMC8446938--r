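Package: htncascade
Title: Bayesian Hierarchical Estimation of the Hypertension Care Cascade from Sparse Population Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for estimating hypertension prevalence and the care cascade
    (detection, treatment, control) from heterogeneous population survey data.
    Applies standard outcome definitions to blood-pressure microdata, computes
    design-based crude age-sex-specific estimates with Kish effective sample
    sizes, pools study estimates across countries, regions and super-regions
    with a Bayesian hierarchical model featuring non-linear (second-order
    random walk) time trends, a natural cubic spline age pattern and
    age-varying trends, fitted by Markov chain Monte Carlo, and post-processes
    posterior surfaces into age-standardised rates, population-weighted
    aggregates, people counts, cascade stage streams and change statistics
    with credible intervals. Includes a synthetic multi-country survey world
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    splines,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
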