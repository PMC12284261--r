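Package: pairgsm
Title: Pairwise Gaussian Scale Mixture Models of V1 Response Covariability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how natural image statistics shape the
    trial-to-trial covariability of pairs of primary visual cortex (V1)
    neurons under the neural sampling hypothesis. Implements pairwise
    Gaussian scale mixture (GSM) image models with a shared or two
    independent multiplicative contrast modulators over steerable-pyramid
    style quadrature filter banks; trains them by moment matching on image
    ensembles; computes posteriors over local features with the modulators
    marginalized (deterministic quadrature oracle and a collapsed
    slice-within-Gibbs sampler); compares model structures by marginal
    likelihood; converts posterior samples to complex-cell spike counts to
    predict surround modulation of pairwise spike-count correlations; and
    provides the matching spike-count data pipeline (receptive-field based
    pair classification, responsivity filtering, mean-matching, factor
    analysis subsampled significance tests, and binned regression). All
    inputs can be generated synthetically for fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    pracma
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    yaml
Config/testthat/edition: 3
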