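#' From posterior samples to spike counts and pairwise correlations
#'
#' Under the sampling hypothesis each posterior draw is one trial of
#' instantaneous neural activity. A phase-invariant (complex-cell)
#' response model converts the two center-filter features of a neuron to a
#' non-negative rate, `r = alpha * (max(g+ + offset, 0) + max(g- + offset,
#' 0))`, optionally rounded to integer spike counts without added spiking
#' noise; pairwise covariability is then the Pearson correlation of the
#' two neurons' responses across draws.
#'
#' @name response_model
NULL

#' Response-model configuration
#'
#' @param alpha gain, spikes per unit feature (> 0). A heuristic scaling
#'   into the measured spike-count range.
#' @param offset additive shift applied to the feature samples before
#'   rectification; reduces clipping for weakly driven stimuli without
#'   changing the direction of contextual effects.
#' @param round_to_counts round responses to integers.
#' @export
response_config <- function(alpha = 10, offset = 0.5,
                            round_to_counts = FALSE) {
  if (alpha <= 0) stop("`alpha` must be positive")
  structure(list(alpha = alpha, offset = offset,
                 round_to_counts = round_to_counts),
            class = "response_config")
}

#' Center-filter quadrature indices for a feature vector of length d
#'
#' Filters are phase-major per neuron: even phases first (center first),
#' then odd phases (center first), so the center pair of neuron `i` sits at
#' `(i-1) m + 1` (even) and `(i-1) m + m/2 + 1` (odd).
#'
#' @param d feature dimension (`2m`, `m` even).
#' @export
default_center_indices <- function(d) {
  m <- d %/% 2L
  if (d %% 2L != 0L || m %% 2L != 0L)
    stop("feature dimension must be 2m with m even to hold quadrature pairs")
  list(even = c(1L, m + 1L), odd = c(m %/% 2L + 1L, m + m %/% 2L + 1L))
}

#' Convert feature samples to responses of the two neurons
#'
#' @param g an `n x d` matrix of feature samples (or a `gsm_posterior`).
#' @param config a [response_config()].
#' @param center list with `even` and `odd` index pairs; defaults to
#'   [default_center_indices()] for the sample dimension.
#' @return An `n x 2` matrix of non-negative responses.
#' @export
samples_to_rates <- function(g, config = response_config(), center = NULL) {
  if (inherits(g, "gsm_posterior")) g <- g$g
  d <- ncol(g)
  if (is.null(center)) center <- default_center_indices(d)
  idx <- c(center$even, center$odd)
  if (any(idx < 1L) || any(idx > d))
    stop("center-filter indices out of range for d = ", d)
  r <- config$alpha *
    (pmax(g[, center$even, drop = FALSE] + config$offset, 0) +
       pmax(g[, center$odd, drop = FALSE] + config$offset, 0))
  if (config$round_to_counts) r <- round(r)
  colnames(r) <- c("r1", "r2")
  r
}

#' Spike-count correlation of two response vectors
#'
#' Pearson correlation across trials/samples. Undefined (returned as `NA`
#' with a warning) when either vector has zero variance.
#'
#' @param r1,r2 equal-length numeric vectors, length >= 3.
#' @export
rsc <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("`r1` and `r2` must have equal length")
  if (length(r1) < 3L) stop("need at least 3 paired samples")
  if (stats::sd(r1) == 0 || stats::sd(r2) == 0) {
    warning("zero variance; spike-count correlation undefined")
    return(NA_real_)
  }
  stats::cor(r1, r2)
}

#' Posterior-expected responses by quadrature
#'
#' Exact expected firing rate under the marginalized posterior: for each
#' modulator grid point the center features are Gaussian, the rectifier
#' expectation `E max(Z + offset, 0)` has a closed form, and the mixture
#' weights combine the components. Deterministic, so suited to tuning
#' curves (signal correlations) where sampling noise would bias Pearson
#' estimates.
#'
#' @param X `n x d` observation matrix.
#' @param params a [gsm_params()].
#' @param config a [response_config()].
#' @param n_grid modulator grid points (per dimension for independent).
#' @return `n x 2` matrix of expected responses.
#' @export
expected_rates <- function(X, params, config = response_config(),
                           n_grid = NULL) {
  if (is.vector(X)) X <- matrix(X, 1)
  d <- ncol(X)
  center <- default_center_indices(d)
  idx <- c(center$even[1], center$odd[1], center$even[2], center$odd[2])
  if (is.null(n_grid))
    n_grid <- if (params$structure == "shared") 96L else 24L
  erect <- function(mu, sd) {
    a <- mu + config$offset
    ifelse(sd <= 0, pmax(a, 0),
           a * stats::pnorm(a / sd) + sd * stats::dnorm(a / sd))
  }
  out <- matrix(0, nrow(X), 2)
  pc <- .gsm_precompute(params)
  grid <- v_grid(params, n_grid)
  if (params$structure == "shared") {
    Y <- .whiten_x(pc, X)                               # d x n
    ll <- .shared_marglik_grid(pc, Y^2, grid)           # n x K
    lw <- stats::dweibull(grid, params$shape, params$scale, log = TRUE) +
      log(trapz_weights(grid))
    W <- exp(sweep(ll, 2, lw, "+") -
               apply(sweep(ll, 2, lw, "+"), 1, logsumexp))  # n x K weights
    A4 <- pc$A[idx, , drop = FALSE]
    for (k in seq_along(grid)) {
      den <- grid[k]^2 * pc$D + 1
      mu4 <- A4 %*% ((grid[k] * pc$D / den) * Y)        # 4 x n
      sd4 <- sqrt(rowSums(sweep(A4^2, 2, pc$D / den, "*")))
      ev <- matrix(erect(t(mu4), rep(sd4, each = nrow(X))), nrow(X), 4)
      out <- out + W[, k] * (ev[, c(1, 3)] + ev[, c(2, 4)])
    }
  } else {
    lw <- stats::dweibull(grid, params$shape, params$scale, log = TRUE) +
      log(trapz_weights(grid))
    K <- length(grid)
    ll <- matrix(0, nrow(X), K * K)
    mu_arr <- array(0, c(nrow(X), 4, K * K))
    sd_arr <- matrix(0, 4, K * K)
    lwij <- numeric(K * K)
    pos <- 1L
    for (i in seq_len(K)) for (j in seq_len(K)) {
      v <- c(grid[i], grid[j])
      ll[, pos] <- .indep_marglik(pc, X, v)
      lwij[pos] <- lw[i] + lw[j]
      s <- .indep_scale_vec(pc, v)
      P <- pc$Sg_inv + (pc$Sn_inv * tcrossprod(s))
      U <- .chol_jitter(P, warn = FALSE)
      Ci <- chol2inv(U)
      mu_all <- t(Ci %*% (s * (pc$Sn_inv %*% t(X))))    # n x d
      mu_arr[, , pos] <- mu_all[, idx]
      sd_arr[, pos] <- sqrt(diag(Ci)[idx])
      pos <- pos + 1L
    }
    llw <- sweep(ll, 2, lwij, "+")
    W <- exp(llw - apply(llw, 1, logsumexp))
    for (pos in seq_len(K * K)) {
      ev <- erect(mu_arr[, , pos, drop = TRUE],
                  rep(sd_arr[, pos], each = nrow(X)))
      ev <- matrix(ev, nrow(X), 4)
      out <- out + W[, pos] * (ev[, c(1, 3)] + ev[, c(2, 4)])
    }
  }
  config$alpha * out
}

#' Simulate a neuron pair's correlations at two stimulus sizes
#'
#' Windows the image at each size, maps it through the filters, samples
#' the marginalized posterior (or, with `marginalize = FALSE`, fixes the
#' modulator at its posterior mode and draws from the Gaussian
#' conditional), converts samples to responses, and reports the
#' spike-count correlation per size and the surround modulation (small
#' minus large).
#'
#' @param image a square gray image.
#' @param geometry a [build_pair_geometry()].
#' @param params a trained [gsm_params()].
#' @param sizes aperture diameters in degrees, `c(small=, large=)`.
#' @param rf_diam_px RF diameter in pixels.
#' @param pixels_per_degree degrees-to-pixels mapping; the default makes
#'   one RF diameter one degree, so the default sizes cover the center
#'   filters only (small) and the center plus surround ring (large).
#' @param response a [response_config()].
#' @param n_samples,chains,warmup,seed sampler settings (see
#'   [sample_posterior()]).
#' @param marginalize if `FALSE`, the modulator is not integrated out but
#'   fixed, once per stimulus, at the mode of its posterior given the
#'   full-context (large) observation; the conditional feature covariance
#'   is then the same for both sizes.
#' @param filter_matrix optional precomputed [pair_filter_matrix()].
#' @return List with `rsc` (named small/large), `modulation`, mean rates
#'   per size, and the sampler diagnostics for each size.
#' @export
simulate_pair <- function(image, geometry, params,
                          sizes = c(small = 1, large = 4),
                          rf_diam_px = 16, pixels_per_degree = rf_diam_px,
                          response = response_config(),
                          n_samples = 2000L, chains = 4L, warmup = 2000L,
                          seed = 1L, marginalize = TRUE,
                          filter_matrix = NULL) {
  out_r <- c(small = NA_real_, large = NA_real_)
  rates <- matrix(NA_real_, 2, 2, dimnames = list(c("small", "large"),
                                                  c("r1", "r2")))
  diags <- list()
  xs <- lapply(c(small = "small", large = "large"), function(s) {
    img <- window_image(image, sizes[[s]], pixels_per_degree)
    as.vector(apply_filters(img, geometry, rf_diam_px, filter_matrix))
  })
  if (!marginalize) {
    # one modulator per stimulus, inferred from the full-context (large)
    # observation: without marginalization the conditional covariance of g
    # cannot depend on the stimulus, which is the point being tested
    vhat <- modulator_mode(xs$large, params)
  }
  # common feature innovations across sizes: each size's samples remain
  # exact posterior draws, but their Monte-Carlo errors correlate, which
  # sharpens the small-minus-large comparison
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_samples * params$d), n_samples, params$d)
  for (s in c("small", "large")) {
    x <- xs[[s]]
    if (marginalize) {
      post <- sample_posterior(x, params, n_samples, chains, warmup, seed,
                               g_innovations = Z)
      g <- post$g
      diags[[s]] <- post$diagnostics
    } else {
      cp <- conditional_posterior(x, params, vhat)
      set.seed(seed)
      g <- chol_mvrnorm(n_samples, cp$mean, .chol_jitter(cp$cov, warn = FALSE))
      diags[[s]] <- list(fixed_modulator = vhat)
    }
    r <- samples_to_rates(g, response)
    out_r[s] <- suppressWarnings(rsc(r[, 1], r[, 2]))
    rates[s, ] <- colMeans(r)
  }
  list(rsc = out_r, modulation = unname(out_r["small"] - out_r["large"]),
       mean_rates = rates, diagnostics = diags)
}

#' Model signal correlation across a probe image set
#'
#' Tuning similarity of the two model neurons: the Pearson correlation of
#' their expected responses across probe images (natural-like images that
#' stimulate the reference horizontal filter).
#'
#' @param geometry a [build_pair_geometry()].
#' @param params a trained [gsm_params()].
#' @param probe_images `p x p x n` stack (n >= 2), typically selected with
#'   [select_probe_images()].
#' @param rf_diam_px RF diameter, pixels.
#' @param response a [response_config()].
#' @param n_grid quadrature points for [expected_rates()].
#' @return Pearson correlation, or `NA` when a neuron's tuning has zero
#'   variance.
#' @export
model_signal_correlation <- function(geometry, params, probe_images,
                                     rf_diam_px = 16,
                                     response = response_config(),
                                     n_grid = NULL) {
  X <- apply_filters(probe_images, geometry, rf_diam_px)
  if (nrow(X) < 2L) stop("need at least 2 probe images")
  R <- expected_rates(X, params, response, n_grid)
  if (stats::sd(R[, 1]) == 0 || stats::sd(R[, 2]) == 0) {
    warning("zero tuning variance; signal correlation undefined")
    return(NA_real_)
  }
  stats::cor(R[, 1], R[, 2])
}

#' Select probe images that stimulate the reference filter
#'
#' Ranks images by the quadrature energy of the reference neuron's center
#' filter pair and keeps the strongest drivers.
#'
#' @param images `p x p x n` stack.
#' @param geometry a [build_pair_geometry()].
#' @param n number of images to keep (default 100).
#' @param rf_diam_px RF diameter, pixels.
#' @export
select_probe_images <- function(images, geometry, n = 100L,
                                rf_diam_px = 16) {
  X <- apply_filters(images, geometry, rf_diam_px)
  ci <- default_center_indices(ncol(X))
  energy <- X[, ci$even[1]]^2 + X[, ci$odd[1]]^2
  keep <- order(energy, decreasing = TRUE)[seq_len(min(n, length(energy)))]
  images[, , sort(keep), drop = FALSE]
}
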