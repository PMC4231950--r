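Package: chipmix
Title: Mixture Models for Inter-Site Heterogeneity in Binned ChIP-seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models per-bin read counts from ChIP-seq input (control)
    libraries as Poisson mixtures over a latent site-specific rate.  Fits
    the Poisson, negative binomial, log-normal Poisson and two-component
    negative binomial (NB-NB) count models, computes the nonparametric
    maximum likelihood estimate of the mixing distribution with the
    constrained Newton method, and provides goodness-of-fit diagnostics:
    distribution recovery, mixing-CDF bounds, total variation distance,
    a zero-inflation scan, and de novo blacklist construction from
    posterior component membership.  Includes a synthetic count
    generator, BED/TSV input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
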