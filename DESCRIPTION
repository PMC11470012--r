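Package: wagglefit
Title: Quantifying Waggle-Dance Recruitment from Honeybee Dancefloor Observations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate how much of a honeybee colony's foraging is
    driven by waggle-dance recruitment rather than individual scouting, using
    only the waggle-run durations decoded from dances on the dancefloor.
    Implements a two-component finite mixture of truncated distributions
    (exponential-type for scout trips, Rayleigh-type for recruit trips) with
    closed-form normalizers and distribution functions, maximum-likelihood
    fitting by multistart Nelder-Mead, AIC and Akaike-weight model selection
    between an individual-search model and a collective-foraging model, and a
    bootstrapped two-sample Kolmogorov-Smirnov goodness-of-fit test. Also
    provides an agent-based central-place foraging simulator that reproduces
    the exponential versus Rayleigh dichotomy of scout and recruit trip
    distances, a synthetic multi-hive study generator with known ground truth,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
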