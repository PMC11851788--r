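Package: isoweb
Title: Stable-Isotope Food-Web Analysis with Bayesian Mixing Models and
    Penalized Additive Smooths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing coastal food webs from bulk carbon and
    nitrogen stable isotopes: delta-notation arithmetic, lipid and spatial
    baseline corrections, Post-style trophic levels with a scaled nitrogen
    trophic enrichment factor, Bayesian stable-isotope mixing models with
    Dirichlet priors and MCMC diagnostics, source merging driven by posterior
    correlations, a continuous-covariate (depth) extension on isometric
    log-ratio transformed diet proportions, and penalized additive smooth
    regression of isotope values on environmental gradients with GCV
    smoothness selection and AICc subset selection. Includes a forward
    simulator for food-web isotope data with known ground truth and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr,
    yaml
Config/testthat/edition: 3
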