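# Shared numerical and bookkeeping helpers.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# trapezoid integration weights on an arbitrary (sorted) grid
trapz_weights <- function(v) {
  n <- length(v)
  if (n == 1L) return(1)
  w <- numeric(n)
  w[1] <- (v[2] - v[1]) / 2
  w[n] <- (v[n] - v[n - 1]) / 2
  if (n > 2L) w[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
  w
}

# symmetrize and floor eigenvalues; returns matrix plus count of clipped ones
psd_project <- function(S, jitter = NULL) {
  S <- (S + t(S)) / 2
  if (is.null(jitter)) jitter <- 1e-8 * sum(diag(S)) / nrow(S)
  e <- eigen(S, symmetric = TRUE)
  clipped <- sum(e$values < jitter)
  if (clipped > 0L) {
    vals <- pmax(e$values, jitter)
    S <- e$vectors %*% (vals * t(e$vectors))
    S <- (S + t(S)) / 2
  }
  attr(S, "clipped_eigenvalues") <- clipped
  S
}

# stamp generated objects with what produced them (seed-deterministic contract)
with_provenance <- function(x, generator, config) {
  attr(x, "provenance") <- list(
    generator = generator,
    config = config,
    id = paste0(generator, ":", paste(deparse(config), collapse = ""))
  )
  x
}

provenance_id <- function(x) {
  p <- attr(x, "provenance")
  if (is.null(p)) NULL else p$id
}

# draw one sample from N(mean, Sigma) given the upper Cholesky factor of Sigma
chol_mvrnorm <- function(n, mean, chol_upper) {
  d <- length(mean)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% chol_upper, 2, mean, "+")
}
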