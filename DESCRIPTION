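Package: cogle
Title: Cognitive Impairment-Free Life Expectancy by Diabetes Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of total life expectancy, life expectancy with and
    without cognitive impairment, and mean age at first onset of cognitive
    impairment by diabetes status from longitudinal panel data. Transition
    probabilities among the states cognitively non-impaired, cognitively
    impaired and dead are estimated with origin-state- and sex-stratified
    multinomial logistic models, fed into a discrete-time Markov chain
    matrix population model, and contrasted across observed, no-diabetes and
    full-diabetes counterfactual scenarios. Includes a synthetic panel
    generator emulating biennial aging-study designs (entry ages 50-74,
    attrition, missing cognition scores, absorbing diabetes diagnosis), a
    microsimulation oracle for the matrix results, and cluster-bootstrap
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
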