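#' MCMC convergence diagnostics
#'
#' Split R-hat and effective sample size computed per dimension from draws
#' stacked over chains, following the standard split-chain formulation:
#' each chain is halved, the potential scale reduction factor compares
#' between- and within-half variances, and the effective sample size uses
#' the within-chain autocorrelations combined by Geyer's initial monotone
#' positive sequence.
#'
#' @param draws an `n x k` matrix of posterior draws (chains stacked
#'   row-wise).
#' @param chain integer vector of length `n` giving each draw's chain.
#' @return Named numeric vector, one entry per column of `draws`.
#' @name diagnostics
NULL

.split_chains <- function(draws, chain) {
  pieces <- list()
  for (ch in unique(chain)) {
    x <- draws[chain == ch, , drop = FALSE]
    h <- nrow(x) %/% 2L
    if (h < 1L) next
    pieces <- c(pieces, list(x[seq_len(h), , drop = FALSE],
                             x[h + seq_len(h), , drop = FALSE]))
  }
  pieces
}

#' @rdname diagnostics
#' @export
split_rhat <- function(draws, chain) {
  draws <- as.matrix(draws)
  pieces <- .split_chains(draws, chain)
  m <- length(pieces)
  n <- nrow(pieces[[1]])
  out <- vapply(seq_len(ncol(draws)), function(j) {
    xs <- vapply(pieces, function(p) mean(p[, j]), numeric(1))
    s2 <- vapply(pieces, function(p) stats::var(p[, j]), numeric(1))
    W <- mean(s2)
    B <- n * stats::var(xs)
    if (W <= 0) return(if (B <= 1e-300) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  names(out) <- colnames(draws)
  out
}

#' @rdname diagnostics
#' @export
ess_mean <- function(draws, chain) {
  draws <- as.matrix(draws)
  pieces <- .split_chains(draws, chain)
  m <- length(pieces)
  n <- nrow(pieces[[1]])
  out <- vapply(seq_len(ncol(draws)), function(j) {
    s2 <- vapply(pieces, function(p) stats::var(p[, j]), numeric(1))
    W <- mean(s2)
    xs <- vapply(pieces, function(p) mean(p[, j]), numeric(1))
    varplus <- (n - 1) / n * W + stats::var(xs)
    if (!is.finite(varplus) || varplus <= 0) return(m * n)
    max_lag <- min(n - 1L, 400L)
    acov <- vapply(pieces, function(p) {
      x <- p[, j] - mean(p[, j])
      vapply(0:max_lag, function(l)
        sum(x[seq_len(n - l)] * x[seq_len(n - l) + l]) / n, numeric(1))
    }, numeric(max_lag + 1L))
    rho <- 1 - (W - rowMeans(acov)) / varplus
    rho[1] <- 1
    # Geyer: sum consecutive-lag pairs while positive and monotone
    tau <- 0
    prev <- Inf
    t <- 1L
    while (t + 1L <= length(rho)) {
      pair <- rho[t] + rho[t + 1L]
      if (pair < 0) break
      pair <- min(pair, prev)
      tau <- tau + pair
      prev <- pair
      t <- t + 2L
    }
    ess <- m * n / max(2 * tau - 1, 1 / (m * n))
    min(ess, m * n * 10)
  }, numeric(1))
  names(out) <- colnames(draws)
  out
}

#' Monte-Carlo standard error of posterior means
#'
#' @param post a `gsm_posterior` from [sample_posterior()].
#' @return Named vector of `sd / sqrt(ESS)` per dimension (features then
#'   modulators).
#' @export
posterior_mc_se <- function(post) {
  stopifnot(inherits(post, "gsm_posterior"))
  draws <- cbind(post$g, post$v)
  colnames(draws) <- names(post$diagnostics$ess)
  apply(draws, 2, stats::sd) / sqrt(pmax(post$diagnostics$ess, 1))
}
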