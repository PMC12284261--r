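#' Forward draws from the pairwise GSM generative model
#'
#' Exact samples of `(x, v, g)` from the generative process: local features
#' `g ~ N(0, Sigma_g)`, modulator(s) `v` from the Weibull prior (one value
#' for the shared structure, one per neuron for the independent structure),
#' additive noise `eta ~ N(0, Sigma_noise)`, and `x = V g + eta`. Latents
#' are returned so recovery of the training and inference stages can be
#' tested against ground truth.
#'
#' @param params a [gsm_params()] object.
#' @param n number of observations.
#' @param seed integer seed; fully determines the draws.
#' @return A list with `x` (`n x 2m`), `v` (`n x 1` or `n x 2`) and `g`
#'   (`n x 2m`), with a provenance attribute on `x`.
#' @export
gen_gsm_observations <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "gsm_params"))
  set.seed(seed)
  d <- params$d
  sqrt_g <- .sym_sqrt(params$Sigma_g)
  sqrt_n <- .sym_sqrt(params$Sigma_noise)
  g <- matrix(stats::rnorm(n * d), n, d) %*% sqrt_g
  eta <- matrix(stats::rnorm(n * d), n, d) %*% sqrt_n
  if (params$structure == "shared") {
    v <- matrix(stats::rweibull(n, params$shape, params$scale), n, 1)
    x <- g * as.vector(v) + eta
  } else {
    v <- matrix(stats::rweibull(2L * n, params$shape, params$scale), n, 2)
    x <- g * v[, rep(1:2, each = params$m)] + eta
  }
  x <- with_provenance(x, "gsm_forward",
                       list(structure = params$structure, n = n, seed = seed))
  list(x = x, v = v, g = g)
}

# symmetric matrix square root tolerating semi-definite input
.sym_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}
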