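#' Pairwise Gaussian scale mixture parameters
#'
#' The pairwise GSM generates an observation vector `x` of length `2m`
#' (filters of neuron 1, then neuron 2) as `x = V g + eta`, where
#' `g ~ N(0, Sigma_g)`, `eta ~ N(0, Sigma_noise)`, and `V` is either `v I`
#' with a single shared modulator `v`, or `diag(v1 I_m, v2 I_m)` with two
#' independent modulators; modulators follow a Weibull prior (default
#' shape 2, scale sqrt(2), i.e. Rayleigh(1) with `E[v^2] = 2`). The
#' independent structure constrains the cross-neuron blocks of `Sigma_g`
#' to zero.
#'
#' @param structure `"shared"` or `"independent"`.
#' @param Sigma_g prior covariance of the local features, `2m x 2m`
#'   symmetric positive semi-definite.
#' @param Sigma_noise additive-noise covariance, same size.
#' @param shape,scale Weibull prior parameters of the modulator(s).
#' @param jitter eigenvalue floor used when validating/repairing PSD-ness;
#'   default `1e-8 * trace / dim`.
#' @return A `gsm_params` object with elements `structure`, `Sigma_g`,
#'   `Sigma_noise`, `shape`, `scale`, `m` (filters per neuron).
#' @export
gsm_params <- function(structure = c("shared", "independent"),
                       Sigma_g, Sigma_noise,
                       shape = 2, scale = sqrt(2), jitter = NULL) {
  structure <- match.arg(structure)
  d <- nrow(Sigma_g)
  if (any(dim(Sigma_g) != d) || any(dim(Sigma_noise) != d))
    stop("covariances must be square and equal-sized")
  if (structure == "independent" && d %% 2L != 0L)
    stop("the independent structure needs an even dimension (two equal blocks)")
  if (max(abs(Sigma_g - t(Sigma_g))) > 1e-10 ||
      max(abs(Sigma_noise - t(Sigma_noise))) > 1e-10)
    stop("covariances must be symmetric (within 1e-10)")
  if (shape <= 0 || scale <= 0) stop("Weibull prior parameters must be positive")
  m <- d %/% 2L
  blk <- function(S) max(abs(S[seq_len(m), m + seq_len(m)]))
  if (structure == "independent" && blk(Sigma_g) > 0)
    stop("independent structure requires exactly zero cross-neuron blocks of Sigma_g")
  check_psd <- function(S, name) {
    ev <- min(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8 * sum(diag(S)))
      stop(name, " is not positive semi-definite (min eigenvalue ", ev, ")")
  }
  check_psd(Sigma_g, "Sigma_g"); check_psd(Sigma_noise, "Sigma_noise")
  out <- list(structure = structure,
              Sigma_g = (Sigma_g + t(Sigma_g)) / 2,
              Sigma_noise = (Sigma_noise + t(Sigma_noise)) / 2,
              shape = shape, scale = scale, m = m, d = d)
  class(out) <- "gsm_params"
  out
}

#' @export
print.gsm_params <- function(x, ...) {
  cat(sprintf("gsm_params: %s modulator, %d filters/neuron, Weibull(%g, %g) prior\n",
              x$structure, x$m, x$shape, x$scale))
  invisible(x)
}

#' Second moment of the Weibull modulator prior
#'
#' `E[v^2] = scale^2 * Gamma(1 + 2/shape)`; equals 2 for the default
#' Rayleigh(1)-equivalent prior.
#'
#' @param shape,scale Weibull parameters.
#' @export
weibull_m2 <- function(shape = 2, scale = sqrt(2)) {
  scale^2 * gamma(1 + 2 / shape)
}

.cross_blocks_scaled <- function(S, m, scale_factor) {
  i1 <- seq_len(m); i2 <- m + seq_len(m)
  S[i1, i2] <- S[i1, i2] * scale_factor
  S[i2, i1] <- S[i2, i1] * scale_factor
  S
}

#' Estimate the additive-noise covariance from white-noise responses
#'
#' Empirical covariance of filter outputs to white-noise images, with the
#' across-neuron 18x18 blocks multiplied by `cross_set_scale` (a free
#' parameter controlling how much additive noise the two model neurons
#' share; 1 leaves the empirical covariance untouched, 0 makes it exactly
#' block-diagonal). The result is PSD-projected; if eigenvalues had to be
#' clipped a warning reports how many.
#'
#' @param white_noise_x an `n x 2m` matrix of observation vectors from
#'   white-noise images (see [gen_white_noise_images()] and
#'   [apply_filters()]).
#' @param cross_set_scale multiplier on the across-neuron covariance blocks.
#' @param jitter optional eigenvalue floor (default `1e-8 * trace / dim`).
#' @return The noise covariance matrix.
#' @export
estimate_noise_cov <- function(white_noise_x, cross_set_scale = 1,
                               jitter = NULL) {
  if (nrow(white_noise_x) < 2L) stop("need at least 2 observations")
  if (cross_set_scale < 0) stop("`cross_set_scale` must be >= 0")
  S <- stats::cov(white_noise_x)
  S <- .cross_blocks_scaled(S, ncol(S) %/% 2L, cross_set_scale)
  S <- psd_project(S, jitter)
  if (attr(S, "clipped_eigenvalues") > 0L)
    warning("noise covariance rank-deficient after cross-set scaling; ",
            attr(S, "clipped_eigenvalues"), " eigenvalue(s) floored")
  S
}

#' Scale images so filter outputs reach a target signal-to-noise ratio
#'
#' Multiplies the (zero-mean part of the) natural images by one scalar so
#' that the ratio of root-mean-square filter output over natural images to
#' that over white-noise images equals `target` (default 4.8). Because the
#' filters have zero mean, scaling pixel contrast about mid-gray scales
#' filter outputs linearly, so the achieved ratio is exact.
#'
#' @param natural_images,noise_images `p x p x n` image stacks.
#' @param geometry a [build_pair_geometry()] object.
#' @param target desired RMS filter-output ratio.
#' @param rf_diam_px receptive-field diameter, pixels.
#' @param filter_matrix optional precomputed filter matrix.
#' @return The scaled natural image stack (contrast about 0.5 multiplied by
#'   the scalar, not clipped); attribute `snr_scalar` records the scalar.
#' @export
scale_images_to_snr <- function(natural_images, noise_images, geometry,
                                target = 4.8, rf_diam_px = 16,
                                filter_matrix = NULL) {
  if (target <= 0) stop("`target` must be positive")
  xn <- apply_filters(natural_images, geometry, rf_diam_px, filter_matrix)
  xw <- apply_filters(noise_images, geometry, rf_diam_px, filter_matrix)
  rms <- function(x) sqrt(mean(x^2))
  if (rms(xw) == 0) stop("white-noise filter outputs have zero RMS")
  if (rms(xn) == 0) stop("natural-image filter outputs have zero RMS")
  s <- target / (rms(xn) / rms(xw))
  out <- 0.5 + s * (natural_images - 0.5)
  attributes(out) <- attributes(natural_images)
  attr(out, "snr_scalar") <- s
  out
}

#' Moment-matching estimate of the feature prior covariance
#'
#' Under the pairwise GSM, `E[x x'] = E[v^2] Sigma_g + Sigma_noise`, so the
#' prior covariance is recovered as `(S_x - Sigma_noise) / E[v^2]` with
#' `S_x` the empirical covariance of the observations. For the independent
#' structure the across-neuron blocks are then set exactly to zero. The
#' difference can be slightly indefinite at finite `n`; negative
#' eigenvalues are floored at the jitter level with a warning reporting the
#' count.
#'
#' @param x an `n x 2m` observation matrix (natural-image filter outputs,
#'   already SNR-scaled).
#' @param Sigma_noise noise covariance from [estimate_noise_cov()].
#' @param structure `"shared"` or `"independent"`.
#' @param shape,scale Weibull prior parameters (fix `E[v^2]`).
#' @param jitter optional eigenvalue floor.
#' @return The estimated `Sigma_g`.
#' @export
estimate_prior_cov <- function(x, Sigma_noise,
                               structure = c("shared", "independent"),
                               shape = 2, scale = sqrt(2), jitter = NULL) {
  structure <- match.arg(structure)
  S <- (stats::cov(x) - Sigma_noise) / weibull_m2(shape, scale)
  if (structure == "independent")
    S <- .cross_blocks_scaled(S, ncol(S) %/% 2L, 0)
  S <- psd_project(S, jitter)
  if (attr(S, "clipped_eigenvalues") > 0L)
    warning("moment-matched prior covariance indefinite; ",
            attr(S, "clipped_eigenvalues"), " eigenvalue(s) floored")
  if (structure == "independent")   # flooring cannot reintroduce cross terms
    S <- .cross_blocks_scaled(S, ncol(S) %/% 2L, 0)
  S
}

#' Train a pairwise GSM on image ensembles
#'
#' Convenience wrapper tying the training stages together: filter the
#' white-noise ensemble, estimate the noise covariance, scale the natural
#' ensemble to the target signal-to-noise ratio, filter it, and
#' moment-match the feature prior covariance.
#'
#' @param natural_images,noise_images `p x p x n` stacks.
#' @param geometry a [build_pair_geometry()] object.
#' @param structure `"shared"` or `"independent"`.
#' @param snr_target RMS filter-output ratio between ensembles.
#' @param cross_set_scale multiplier on across-neuron noise covariance.
#' @param shape,scale Weibull modulator prior.
#' @param rf_diam_px receptive-field diameter, pixels.
#' @return A [gsm_params()] object; attribute `snr_scalar` records the
#'   image scaling applied.
#' @export
train_pair_gsm <- function(natural_images, noise_images, geometry,
                           structure = c("shared", "independent"),
                           snr_target = 4.8, cross_set_scale = 1,
                           shape = 2, scale = sqrt(2), rf_diam_px = 16) {
  structure <- match.arg(structure)
  Fm <- pair_filter_matrix(geometry, dim(noise_images)[1], rf_diam_px)
  xw <- apply_filters(noise_images, geometry, rf_diam_px, Fm)
  Sn <- estimate_noise_cov(xw, cross_set_scale)
  nat <- scale_images_to_snr(natural_images, noise_images, geometry,
                             snr_target, rf_diam_px, Fm)
  xn <- apply_filters(nat, geometry, rf_diam_px, Fm)
  Sg <- estimate_prior_cov(xn, Sn, structure, shape, scale)
  p <- gsm_params(structure, Sg, Sn, shape, scale)
  attr(p, "snr_scalar") <- attr(nat, "snr_scalar")
  attr(p, "train_provenance") <- list(natural = provenance_id(natural_images),
                                      noise = provenance_id(noise_images))
  p
}

#' Train a pairwise GSM from precomputed filter outputs
#'
#' Same estimator as [train_pair_gsm()], but starting from observation
#' matrices instead of image stacks, so large ensembles can be filtered
#' once per geometry (or in batches) and reused across structures. The
#' natural-image outputs are rescaled by one scalar to the target RMS
#' signal-to-noise ratio against the white-noise outputs; by linearity of
#' the filters this is identical to rescaling the images.
#'
#' @param natural_x,noise_x `n x 2m` observation matrices from
#'   [apply_filters()].
#' @inheritParams train_pair_gsm
#' @return A [gsm_params()] object with attribute `snr_scalar`.
#' @export
train_pair_gsm_obs <- function(natural_x, noise_x,
                               structure = c("shared", "independent"),
                               snr_target = 4.8, cross_set_scale = 1,
                               shape = 2, scale = sqrt(2)) {
  structure <- match.arg(structure)
  Sn <- estimate_noise_cov(noise_x, cross_set_scale)
  rms <- function(x) sqrt(mean(x^2))
  if (rms(noise_x) == 0) stop("white-noise filter outputs have zero RMS")
  s <- snr_target / (rms(natural_x) / rms(noise_x))
  Sg <- estimate_prior_cov(s * natural_x, Sn, structure, shape, scale)
  p <- gsm_params(structure, Sg, Sn, shape, scale)
  attr(p, "snr_scalar") <- s
  p
}

#' Derive the independent-structure model from a shared fit
#'
#' The independent prior covariance is the shared one with the
#' across-neuron blocks set exactly to zero (each neuron's within-set
#' covariances are retained); the noise covariance and prior are carried
#' over.
#'
#' @param params a shared-structure [gsm_params()].
#' @export
as_independent <- function(params) {
  stopifnot(inherits(params, "gsm_params"))
  if (params$structure != "shared")
    stop("`params` must be a shared-structure model")
  Sg <- .cross_blocks_scaled(params$Sigma_g, params$m, 0)
  p <- gsm_params("independent", Sg, params$Sigma_noise,
                  params$shape, params$scale)
  attr(p, "snr_scalar") <- attr(params, "snr_scalar")
  p
}
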