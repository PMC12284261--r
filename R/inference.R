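#' Posterior inference in the pairwise GSM
#'
#' Conditional on the modulator(s) the pairwise GSM is linear-Gaussian, so
#' the posterior over local features `g` is an (infinite) mixture of
#' Gaussians indexed by the modulator value. This module exposes that
#' structure three ways: exact conditional posteriors at fixed modulator
#' values, a deterministic quadrature oracle over a modulator grid (the
#' reference implementation), and a collapsed slice-within-Gibbs sampler
#' that draws the modulator(s) from their exact marginal posterior by
#' slice sampling and the features from the exact Gaussian conditional.
#' Marginal likelihoods for shared-versus-independent model comparison use
#' the same quadrature.
#'
#' @name inference
NULL

# ---- shared precomputations -------------------------------------------------

# Cholesky with a trace-scaled jitter fallback
.chol_jitter <- function(S, warn = TRUE) {
  tryCatch(chol(S), error = function(e) {
    j <- 1e-10 * max(sum(diag(S)), 1) / nrow(S)
    if (warn) warning("singular covariance; jitter ", signif(j, 3), " added")
    chol(S + diag(j + 1e-300, nrow(S)))
  })
}

# Whitened/rotated representation. For the shared structure the noise-
# whitened prior M = L^-1 Sigma_g L^-T is diagonalized once, after which
# every per-modulator quantity (marginal log-density, conditional mean and
# variance of g) costs O(d).
.gsm_precompute <- function(params) {
  d <- params$d
  U <- .chol_jitter(params$Sigma_noise)
  L <- t(U)                                        # lower factor
  logdet_Sn <- 2 * sum(log(diag(U)))
  Sn_inv <- chol2inv(U)
  pc <- list(params = params, d = d, L = L, logdet_Sn = logdet_Sn,
             Sn_inv = Sn_inv)
  if (params$structure == "shared") {
    M <- forwardsolve(L, t(forwardsolve(L, params$Sigma_g)))
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    pc$D <- pmax(e$values, 0)
    pc$A <- L %*% e$vectors                        # g = A %*% g_hat
    pc$rot <- t(e$vectors)                         # y = rot %*% L^-1 x
  } else {
    Ug <- .chol_jitter(params$Sigma_g, warn = FALSE)
    pc$Sg_inv <- chol2inv(Ug)
  }
  pc
}

.whiten_x <- function(pc, X) {
  # X: n x d; returns d x n matrix y in the rotated whitened basis
  pc$rot %*% forwardsolve(pc$L, t(X))
}

# log N(x; 0, v^2 Sigma_g + Sigma_noise) for all grid values, shared case;
# y2 is d x n matrix of squared rotated coordinates
.shared_marglik_grid <- function(pc, y2, vs) {
  d <- pc$d
  n <- ncol(y2)
  out <- vapply(vs, function(v) {
    den <- v^2 * pc$D + 1
    -0.5 * (d * log(2 * pi) + pc$logdet_Sn + sum(log(den)) +
              colSums(y2 / den))
  }, numeric(n))
  matrix(out, n, length(vs))                       # n x K (K = length(vs))
}

.indep_scale_vec <- function(pc, v) rep(v, each = pc$params$m)

# log N(x; 0, V Sigma_g V + Sigma_noise) for the independent structure
.indep_marglik <- function(pc, X, v) {
  s <- .indep_scale_vec(pc, v)
  S <- pc$params$Sigma_g * tcrossprod(s) + pc$params$Sigma_noise
  U <- .chol_jitter(S, warn = FALSE)
  z <- forwardsolve(t(U), t(X))
  -0.5 * (pc$d * log(2 * pi)) - sum(log(diag(U))) - 0.5 * colSums(z^2)
}

# ---- modulator grid ---------------------------------------------------------

#' Log-spaced quadrature grid over the modulator prior
#'
#' @param params a [gsm_params()] object (only the prior matters).
#' @param n_grid number of points.
#' @param q_tail prior tail probability excluded on each side.
#' @return Increasing vector of modulator values.
#' @export
v_grid <- function(params, n_grid = 128L, q_tail = 1e-6) {
  qs <- stats::qweibull(c(q_tail, 1 - q_tail), params$shape, params$scale)
  exp(seq(log(qs[1]), log(qs[2]), length.out = n_grid))
}

.check_tail <- function(w_boundary, tail_tol) {
  if (w_boundary > tail_tol)
    stop("modulator posterior mass on the grid boundary (", signif(w_boundary, 3),
         ") exceeds ", tail_tol,
         "; extend the grid (larger n_grid or smaller q_tail)")
}

# ---- conditional posterior --------------------------------------------------

#' Exact conditional posterior of the features at fixed modulator values
#'
#' With the modulator(s) fixed the model is linear-Gaussian and the
#' posterior of `g` is Gaussian: `mean = Sigma_g V (V Sigma_g V +
#' Sigma_noise)^-1 x`, `cov = Sigma_g - Sigma_g V (V Sigma_g V +
#' Sigma_noise)^-1 V Sigma_g`.
#'
#' @param x observation vector, length `2m`.
#' @param params a [gsm_params()] object.
#' @param v modulator value(s): scalar for `"shared"`, length 2 for
#'   `"independent"`; all components must be positive.
#' @return List with `mean` (length `2m`) and `cov` (`2m x 2m`).
#' @export
conditional_posterior <- function(x, params, v) {
  stopifnot(inherits(params, "gsm_params"))
  nv <- if (params$structure == "shared") 1L else 2L
  if (length(v) != nv || any(v <= 0))
    stop("`v` must be ", nv, " positive value(s) for the ", params$structure,
         " structure")
  s <- rep(v, each = if (nv == 1L) params$d else params$m)
  SgV <- sweep(params$Sigma_g, 2, s, "*")          # Sigma_g V
  S <- sweep(SgV, 1, s, "*") + params$Sigma_noise  # V Sigma_g V + Sn
  U <- .chol_jitter(S)
  K <- t(backsolve(U, forwardsolve(t(U), t(SgV)))) # Sigma_g V S^-1
  mean <- as.vector(K %*% x)
  cov <- params$Sigma_g - K %*% t(SgV)
  list(mean = mean, cov = (cov + t(cov)) / 2)
}

# conditional moments in the rotated basis (shared structure), O(d)
.shared_cond_rotated <- function(pc, y, v) {
  den <- v^2 * pc$D + 1
  list(mean = v * pc$D * y / den, var = pc$D / den)
}

# conditional mean/cov for the independent structure via the precision form
.indep_cond <- function(pc, x, v) {
  s <- .indep_scale_vec(pc, v)
  P <- pc$Sg_inv + (pc$Sn_inv * tcrossprod(s))
  U <- .chol_jitter(P, warn = FALSE)
  rhs <- s * (pc$Sn_inv %*% x)
  mean <- backsolve(U, forwardsolve(t(U), rhs))
  list(mean = as.vector(mean), U_prec = U)         # cov = P^-1
}

# ---- quadrature oracle ------------------------------------------------------

#' Deterministic quadrature oracle for the marginalized posterior
#'
#' Represents `p(g | x)` exactly as a mixture of the linear-Gaussian
#' conditionals over a modulator grid, with weights proportional to
#' `p(v) N(x; 0, V Sigma_g V + Sigma_noise)` times trapezoid widths, and
#' returns the mixture mean and covariance. This is the reference against
#' which the stochastic sampler is validated. The normalized weight on the
#' grid boundary is audited; if it exceeds `tail_tol` an error instructs
#' extending the grid. A single-point grid reduces exactly to
#' [conditional_posterior()].
#'
#' @param x observation vector.
#' @param params a [gsm_params()] object.
#' @param n_grid grid points per modulator dimension (128 for shared, 64
#'   per dimension for independent are the defaults).
#' @param grid optional explicit modulator grid (vector); overrides
#'   `n_grid`. A length-1 grid is treated as a degenerate (point-mass)
#'   prior.
#' @param q_tail prior tail probability excluded by the default grid.
#' @param tail_tol maximal tolerated normalized boundary weight.
#' @return List with `mean`, `cov`, `grid`, and `weights` (normalized;
#'   vector for shared, matrix for independent).
#' @export
posterior_oracle <- function(x, params, n_grid = NULL, grid = NULL,
                             q_tail = 1e-6, tail_tol = 1e-6) {
  stopifnot(inherits(params, "gsm_params"))
  pc <- .gsm_precompute(params)
  shared <- params$structure == "shared"
  if (is.null(grid)) {
    if (is.null(n_grid)) n_grid <- if (shared) 128L else 64L
    grid <- v_grid(params, n_grid, q_tail)
  }
  K <- length(grid)
  if (shared) {
    if (K == 1L) {
      cp <- conditional_posterior(x, params, grid)
      return(list(mean = cp$mean, cov = cp$cov, grid = grid, weights = 1))
    }
    y <- as.vector(.whiten_x(pc, matrix(x, 1)))
    logw <- .shared_marglik_grid(pc, matrix(y^2, ncol = 1), grid)[1, ] +
      stats::dweibull(grid, params$shape, params$scale, log = TRUE) +
      log(trapz_weights(grid))
    w <- exp(logw - logsumexp(logw))
    .check_tail(w[1] + w[K], tail_tol)
    den <- outer(pc$D, grid^2, function(D, v2) v2 * D + 1)   # d x K
    mhat <- (outer(pc$D * y, grid) / den)                    # component means
    vhat <- pc$D / den                                       # component vars
    m_rot <- as.vector(mhat %*% w)
    # mixture covariance is diagonal-plus-spread in the rotated basis
    C_rot <- diag(as.vector(vhat %*% w)) +
      (mhat - m_rot) %*% (w * t(mhat - m_rot))
    mean <- as.vector(pc$A %*% m_rot)
    cov <- pc$A %*% C_rot %*% t(pc$A)
    return(list(mean = mean, cov = (cov + t(cov)) / 2,
                grid = grid, weights = w))
  }
  # independent structure: tensor-product grid
  if (K == 1L) {
    cp <- conditional_posterior(x, params, c(grid, grid))
    return(list(mean = cp$mean, cov = cp$cov, grid = grid,
                weights = matrix(1, 1, 1)))
  }
  X1 <- matrix(x, 1)
  lw_prior <- stats::dweibull(grid, params$shape, params$scale, log = TRUE) +
    log(trapz_weights(grid))
  logw <- matrix(0, K, K)
  means <- array(0, c(K, K, pc$d))
  covs <- vector("list", K * K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    v <- c(grid[i], grid[j])
    logw[i, j] <- .indep_marglik(pc, X1, v) + lw_prior[i] + lw_prior[j]
    cnd <- .indep_cond(pc, x, v)
    means[i, j, ] <- cnd$mean
    covs[[(i - 1L) * K + j]] <- chol2inv(cnd$U_prec)
  }
  w <- exp(logw - logsumexp(as.vector(logw)))
  .check_tail(sum(w[1, ]) + sum(w[K, ]) + sum(w[-c(1, K), 1]) +
                sum(w[-c(1, K), K]), tail_tol)
  Mm <- matrix(means, K * K, pc$d)
  wv <- as.vector(t(w))    # covs list is j-fastest; means matrix is i-fastest
  wv_means <- as.vector(w)
  mean <- as.vector(crossprod(Mm, wv_means))
  C <- Reduce("+", Map("*", covs, wv))
  dm <- sweep(Mm, 2, mean)
  cov <- C + crossprod(dm, dm * wv_means)
  list(mean = mean, cov = (cov + t(cov)) / 2, grid = grid, weights = w)
}

# ---- marginal likelihood ----------------------------------------------------

#' Marginal log-likelihood of observations under a pairwise GSM
#'
#' Integrates the linear-Gaussian likelihood over the modulator prior by
#' trapezoid quadrature on a log-spaced grid (one-dimensional for the
#' shared structure, a tensor-product grid for the independent one), with
#' log-domain accumulation. A single-point `grid` gives the point-mass
#' (degenerate prior) log-density exactly.
#'
#' @param x observation vector or `n x 2m` matrix.
#' @inheritParams posterior_oracle
#' @return Numeric vector of per-observation log marginal likelihoods.
#' @export
marginal_loglik <- function(x, params, n_grid = NULL, grid = NULL,
                            q_tail = 1e-6, tail_tol = 1e-6) {
  stopifnot(inherits(params, "gsm_params"))
  if (is.vector(x)) x <- matrix(x, 1)
  pc <- .gsm_precompute(params)
  shared <- params$structure == "shared"
  if (is.null(grid)) {
    if (is.null(n_grid)) n_grid <- if (shared) 128L else 64L
    grid <- v_grid(params, n_grid, q_tail)
  }
  K <- length(grid)
  if (shared) {
    y2 <- .whiten_x(pc, x)^2
    ll <- .shared_marglik_grid(pc, y2, grid)       # n x K
    if (K == 1L) return(as.vector(ll))
    lw <- stats::dweibull(grid, params$shape, params$scale, log = TRUE) +
      log(trapz_weights(grid))
    lse <- apply(sweep(ll, 2, lw, "+"), 1, logsumexp)
    wb <- max(exp(ll[, 1] + lw[1] - lse) + exp(ll[, K] + lw[K] - lse))
    .check_tail(wb, tail_tol)
    return(lse)
  }
  if (K == 1L) return(.indep_marglik(pc, x, c(grid, grid)))
  lw <- stats::dweibull(grid, params$shape, params$scale, log = TRUE) +
    log(trapz_weights(grid))
  n <- nrow(x)
  # streaming log-sum-exp over the K^2 grid keeps memory at O(n)
  M <- rep(-Inf, n); S <- numeric(n); Sb <- numeric(n)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    c_ij <- .indep_marglik(pc, x, c(grid[i], grid[j])) + lw[i] + lw[j]
    Mn <- pmax(M, c_ij)
    scl <- ifelse(is.finite(M), exp(M - Mn), 0)
    term <- exp(c_ij - Mn)
    S <- S * scl + term
    Sb <- Sb * scl + if (i == 1L || i == K || j == 1L || j == K) term else 0
    M <- Mn
  }
  .check_tail(max(Sb / S), tail_tol)
  M + log(S)
}

#' Shared-minus-independent log-likelihood ratio
#'
#' @param x observation vector or matrix.
#' @param shared_params,indep_params trained [gsm_params()] of the two
#'   structures.
#' @param ... passed to [marginal_loglik()].
#' @return Data frame with per-observation `loglik_shared`,
#'   `loglik_independent` and their difference `ratio` (shared minus
#'   independent, exactly).
#' @export
loglik_ratio <- function(x, shared_params, indep_params, ...) {
  if (shared_params$structure != "shared" ||
      indep_params$structure != "independent")
    stop("pass a shared-structure and an independent-structure model, in that order")
  ls <- marginal_loglik(x, shared_params, ...)
  li <- marginal_loglik(x, indep_params, ...)
  data.frame(image = seq_along(ls), loglik_shared = ls,
             loglik_independent = li, ratio = ls - li)
}

# ---- collapsed sampler ------------------------------------------------------

# univariate slice sampler (Neal 2003), stepping out + shrinkage, on an
# unbounded coordinate
.slice1 <- function(x0, logf, w = 1, max_steps = 50L) {
  f0 <- logf(x0)
  z <- f0 - stats::rexp(1)
  lo <- x0 - w * stats::runif(1)
  hi <- lo + w
  k <- max_steps
  while (k > 0L && logf(lo) > z) { lo <- lo - w; k <- k - 1L }
  k <- max_steps
  while (k > 0L && logf(hi) > z) { hi <- hi + w; k <- k - 1L }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

#' Sample the marginalized posterior over features and modulators
#'
#' Collapsed slice-within-Gibbs sampling of `p(g, v | x)`: the
#' modulator(s) are updated by slice sampling on `log v` under the exact
#' marginal posterior `p(v | x)` (prior times the linear-Gaussian evidence,
#' with the features integrated out analytically; the log transform handles
#' positivity, with its Jacobian), and `g` is then drawn exactly from the
#' Gaussian conditional `p(g | v, x)`. Because `g` never enters the
#' modulator update, the `v` chain mixes as a one- (or two-) dimensional
#' chain and the `g` draws add no autocorrelation beyond it.
#'
#' @param x observation vector, length `2m`.
#' @param params a [gsm_params()] object.
#' @param n_samples total posterior draws across chains (must be a
#'   multiple of `chains`).
#' @param chains number of independent chains.
#' @param warmup per-chain warmup iterations, discarded.
#' @param seed integer seed; chain `c` uses `seed + c`, so results are
#'   fully reproducible.
#' @param g_innovations optional `n_samples x d` matrix of standard-normal
#'   innovations used for the feature draws (the modulator chain keeps its
#'   own randomness). Supplying the same matrix to runs on different
#'   observations couples their feature noise (common random numbers),
#'   which sharpens paired comparisons without changing any marginal.
#' @return A `gsm_posterior` object: `g` (`n_samples x 2m`), `v`
#'   (`n_samples x 1` or `x 2`), `chain` (integer vector), and
#'   `diagnostics` with per-dimension split R-hat and effective sample
#'   sizes; dimensions with R-hat above 1.05 are listed in
#'   `diagnostics$flagged` (a warning is emitted but the result is
#'   returned).
#' @export
sample_posterior <- function(x, params, n_samples = 2000L, chains = 4L,
                             warmup = 2000L, seed = 1L,
                             g_innovations = NULL) {
  stopifnot(inherits(params, "gsm_params"))
  if (n_samples < chains) stop("`n_samples` must be at least `chains`")
  n_per <- n_samples %/% chains
  if (n_per * chains != n_samples)
    stop("`n_samples` must be a multiple of `chains`")
  if (!is.null(g_innovations) &&
      !all(dim(g_innovations) == c(n_samples, length(x))))
    stop("`g_innovations` must be an n_samples x d matrix")
  pc <- .gsm_precompute(params)
  shared <- params$structure == "shared"
  d <- pc$d
  if (length(x) != d) stop("`x` must have length ", d)
  nv <- if (shared) 1L else 2L

  if (shared) {
    y <- as.vector(.whiten_x(pc, matrix(x, 1)))
  }

  g_all <- matrix(0, n_samples, d)
  v_all <- matrix(0, n_samples, nv)
  chain_id <- rep(seq_len(chains), each = n_per)
  u_med <- log(stats::qweibull(0.5, params$shape, params$scale))

  for (ch in seq_len(chains)) {
    set.seed(seed + ch)
    rows <- (ch - 1L) * n_per + seq_len(n_per)
    if (shared) {
      u <- u_med + stats::rnorm(1, 0, 0.5)   # overdispersed chain starts
      vs <- .shared_v_chain_cpp(pc$D, y^2, params$shape, params$scale,
                                n_per, warmup, u)
      v_all[rows, 1] <- vs
      den <- outer(vs^2, pc$D) + 1                      # n_per x d
      mhat <- sweep(1 / den * outer(vs, pc$D), 2, y, "*")
      zc <- if (is.null(g_innovations)) matrix(stats::rnorm(n_per * d), n_per, d)
            else g_innovations[rows, , drop = FALSE]
      ghat <- mhat + zc * sqrt(sweep(1 / den, 2, pc$D, "*"))
      g_all[rows, ] <- ghat %*% t(pc$A)
    } else {
      u <- u_med + stats::rnorm(2, 0, 0.5)
      res <- .indep_chain_cpp(x, params$Sigma_g, params$Sigma_noise,
                              pc$Sg_inv, pc$Sn_inv, params$shape,
                              params$scale, params$m, n_per, warmup,
                              u[1], u[2], 1.0,
                              if (is.null(g_innovations)) NULL
                              else g_innovations[rows, , drop = FALSE])
      v_all[rows, ] <- res$v
      g_all[rows, ] <- res$g
    }
  }

  draws <- cbind(g_all, v_all)
  colnames(draws) <- c(paste0("g", seq_len(d)), paste0("v", seq_len(nv)))
  rhat <- split_rhat(draws, chain_id)
  ess <- ess_mean(draws, chain_id)
  flagged <- names(rhat)[is.finite(rhat) & rhat > 1.05]
  if (length(flagged))
    warning("split R-hat above 1.05 for: ", paste(flagged, collapse = ", "))
  out <- list(g = g_all, v = v_all, chain = chain_id,
              diagnostics = list(rhat = rhat, ess = ess, flagged = flagged),
              n_samples = n_samples, chains = chains, warmup = warmup,
              seed = seed, structure = params$structure)
  class(out) <- "gsm_posterior"
  out
}

#' @export
print.gsm_posterior <- function(x, ...) {
  cat(sprintf("gsm_posterior: %d draws x %d chains (%s structure); max split R-hat %.3f\n",
              x$n_samples / x$chains, x$chains, x$structure,
              suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE))))
  invisible(x)
}

#' Posterior mode of the modulator(s)
#'
#' Maximizes the exact marginal posterior `p(v | x)` (grid search refined
#' by numerical optimization). Used to study what inference loses when the
#' modulator is fixed instead of marginalized.
#'
#' @inheritParams posterior_oracle
#' @return Scalar (shared) or length-2 vector (independent).
#' @export
modulator_mode <- function(x, params, n_grid = 256L) {
  pc <- .gsm_precompute(params)
  lp <- function(v) {
    pr <- sum(stats::dweibull(v, params$shape, params$scale, log = TRUE))
    if (params$structure == "shared")
      .shared_marglik_grid(pc, .whiten_x(pc, matrix(x, 1))^2, v)[1, ] + pr
    else .indep_marglik(pc, matrix(x, 1), v) + pr
  }
  grid <- v_grid(params, n_grid)
  if (params$structure == "shared") {
    vals <- vapply(grid, lp, numeric(1))
    v0 <- grid[which.max(vals)]
    stats::optimize(function(v) lp(v), c(v0 / 2, v0 * 2), maximum = TRUE)$maximum
  } else {
    vals <- outer(grid, grid, Vectorize(function(a, b) lp(c(a, b))))
    ij <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    v0 <- c(grid[ij[1]], grid[ij[2]])
    exp(stats::optim(log(v0), function(u) -lp(exp(u)))$par)
  }
}
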