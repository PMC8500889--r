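Package: exemplarmix
Title: Latent-Mixture Exemplar Models of Multiple-Cue Judgment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying exemplar-based models of continuous
    multiple-cue judgment and the bias that direct recall of trained
    exemplars induces in the similarity parameter of the context model.
    Provides the similarity-weighted exemplar prediction rule, a latent
    -mixture extension that separates similarity-based judgment from
    direct recall of learned criterion values, a synthetic judgment-data
    generator emulating typical multiple-cue judgment experiments,
    adaptive MCMC estimation of both models, Savage-Dickey Bayes factors,
    posterior-predictive RMSE model comparison, and a Monte-Carlo
    parameter-recovery pipeline over a grid of true similarity values and
    recall probabilities.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    optparse,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rjags,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
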