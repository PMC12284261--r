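#' Synthetic image ensembles
#'
#' Generators for the image inputs the pipeline needs: white-noise images
#' (for additive-noise covariance estimation) and surrogate "natural-like"
#' images built from homogeneous textures with region-wise multiplicative
#' contrast, the non-stationary structure a Gaussian scale mixture assumes.
#' All generators are seed-deterministic and stamp a provenance attribute
#' (generator, config, id) on their output.
#'
#' @name synthetic_images
NULL

#' Generate white-noise images
#'
#' I.i.d. Gaussian pixels with target mean 0.5 and standard deviation 0.1,
#' clipped to `[0, 1]` (the clipped fraction is recorded in the provenance
#' attribute; at sd 0.1 it is ~ 5e-7).
#'
#' @param n number of images.
#' @param size patch side, pixels.
#' @param seed integer seed; fully determines the stack.
#' @param mean,sd target pixel mean and standard deviation.
#' @return A `size x size x n` array in `[0, 1]` with a provenance attribute.
#' @export
gen_white_noise_images <- function(n, size = 64, seed = 1L,
                                   mean = 0.5, sd = 0.1) {
  if (n < 1) stop("`n` must be >= 1")
  set.seed(seed)
  x <- array(stats::rnorm(n * size^2, mean, sd), c(size, size, n))
  clip_frac <- base::mean(x < 0 | x > 1)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x <- with_provenance(x, "white_noise",
                       list(n = n, size = size, seed = seed,
                            mean = mean, sd = sd))
  attr(x, "provenance")$clip_fraction <- clip_frac
  x
}

#' Configuration for surrogate natural-like images
#'
#' @param size patch side, pixels.
#' @param layout `"single"` (one global contrast multiplier, the structure
#'   the shared-modulator model assumes) or `"split"` (two independent
#'   multipliers for the left and right halves, the independent-modulator
#'   structure).
#' @param texture base texture: `"pink"` (1/f amplitude spectrum) or
#'   `"oriented"` (pink noise band-passed around `texture_orientation`).
#' @param texture_orientation degrees, used when `texture = "oriented"`.
#' @param contrast_shape,contrast_scale Weibull parameters of the positive
#'   per-region contrast multiplier; the defaults match the modulator prior
#'   of the generative model (Rayleigh(1)).
#' @param amplitude pixel-contrast amplitude of a unit-contrast texture.
#' @param seed integer seed.
#' @return A `surrogate_config` list.
#' @export
surrogate_image_config <- function(size = 64,
                                   layout = c("single", "split"),
                                   texture = c("pink", "oriented"),
                                   texture_orientation = 0,
                                   contrast_shape = 2,
                                   contrast_scale = sqrt(2),
                                   amplitude = 0.12,
                                   seed = 1L) {
  cfg <- list(size = size, layout = match.arg(layout),
              texture = match.arg(texture),
              texture_orientation = texture_orientation,
              contrast_shape = contrast_shape,
              contrast_scale = contrast_scale,
              amplitude = amplitude, seed = as.integer(seed))
  if (cfg$contrast_shape <= 0 || cfg$contrast_scale <= 0)
    stop("contrast multiplier parameters must be positive")
  class(cfg) <- "surrogate_config"
  cfg
}

# standardized texture field with ~1/f amplitude spectrum, optionally
# band-limited in orientation
.texture_field <- function(size, texture, orientation_deg) {
  fx <- stats::fft(matrix(stats::rnorm(size^2), size, size))
  f1 <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  FX <- matrix(f1, size, size)
  FY <- matrix(f1, size, size, byrow = TRUE)
  rho <- sqrt(FX^2 + FY^2)
  amp <- 1 / pmax(rho, 1 / size)
  amp[1, 1] <- 0
  if (texture == "oriented") {
    th <- orientation_deg * pi / 180
    # energy concentrated where the wave vector is perpendicular to stripes
    ang <- atan2(FY, FX)
    amp <- amp * exp(-(sin(ang - (th + pi / 2)))^2 / (2 * 0.25^2))
  }
  f <- Re(stats::fft(fx * amp, inverse = TRUE)) / size^2
  (f - mean(f)) / stats::sd(f)
}

#' Generate surrogate natural-like images
#'
#' Each image is a homogeneous random texture multiplied region-wise by a
#' positive contrast sample: with a `"single"` layout one global multiplier
#' scales the whole patch; with a `"split"` layout the left and right
#' halves get independent multipliers. Pixels are `0.5 + amplitude *
#' contrast * texture`, clipped to `[0, 1]`.
#'
#' @param config a [surrogate_image_config()].
#' @param n number of images.
#' @return A `size x size x n` array in `[0, 1]` with provenance attribute;
#'   the sampled contrast multipliers are attached as attribute `contrast`
#'   (an `n x 2` matrix, both columns equal for single layouts).
#' @export
gen_surrogate_images <- function(config, n) {
  stopifnot(inherits(config, "surrogate_config"))
  set.seed(config$seed)
  p <- config$size
  half <- seq_len(p %/% 2)
  out <- array(0.5, c(p, p, n))
  cm <- matrix(0, n, 2)
  # shape = Inf denotes the degenerate (constant-contrast) limit
  rcontrast <- function(k) {
    if (is.infinite(config$contrast_shape)) rep(config$contrast_scale, k)
    else stats::rweibull(k, config$contrast_shape, config$contrast_scale)
  }
  for (i in seq_len(n)) {
    tex <- .texture_field(p, config$texture, config$texture_orientation)
    if (config$layout == "single") {
      v <- rcontrast(1)
      cm[i, ] <- v
      img <- 0.5 + config$amplitude * v * tex
    } else {
      v <- rcontrast(2)
      cm[i, ] <- v
      img <- 0.5 + config$amplitude * tex
      img[, half] <- 0.5 + config$amplitude * v[1] * tex[, half]
      img[, -half] <- 0.5 + config$amplitude * v[2] * tex[, -half]
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    out[, , i] <- img
  }
  out <- with_provenance(out, "surrogate_images", unclass(config))
  attr(out, "contrast") <- cm
  out
}

#' Rotate a square image about its center
#'
#' Bilinear interpolation; source pixels falling outside the image are
#' filled with `fill` (mean gray), so only the inscribed central region is
#' valid after a 45-degree rotation.
#'
#' @param image a `p x p` matrix.
#' @param angle_deg rotation angle, degrees counterclockwise.
#' @param fill value for out-of-source pixels.
#' @return The rotated `p x p` matrix.
#' @export
rotate_image <- function(image, angle_deg, fill = 0.5) {
  p <- nrow(image)
  if (ncol(image) != p) stop("`image` must be square")
  th <- angle_deg * pi / 180
  ctr <- (p + 1) / 2
  xs <- seq_len(p) - ctr
  X <- matrix(xs, p, p, byrow = TRUE)
  Y <- matrix(xs, p, p)
  # inverse map: rotate target coords by -angle to find source coords
  sx <- cos(th) * X + sin(th) * Y + ctr
  sy <- -sin(th) * X + cos(th) * Y + ctr
  ok <- sx >= 1 & sx <= p & sy >= 1 & sy <= p
  x0 <- pmin(pmax(floor(sx), 1), p - 1)
  y0 <- pmin(pmax(floor(sy), 1), p - 1)
  wx <- sx - x0; wy <- sy - y0
  out <- matrix(fill, p, p)
  idx <- function(r, c) image[cbind(r[ok], c[ok])]
  vals <- (1 - wx[ok]) * (1 - wy[ok]) * idx(y0, x0) +
    wx[ok] * (1 - wy[ok]) * idx(y0, x0 + 1) +
    (1 - wx[ok]) * wy[ok] * idx(y0 + 1, x0) +
    wx[ok] * wy[ok] * idx(y0 + 1, x0 + 1)
  out[ok] <- vals
  out
}

#' Augment an image stack by 45-degree rotations
#'
#' Each image contributes four copies rotated by 0, 45, 90 and 135 degrees,
#' flattening the ensemble's orientation-energy distribution (cardinal
#' biases of natural images would otherwise make filter statistics depend
#' on absolute orientation).
#'
#' @param images a `p x p x n` array of square patches.
#' @param fill gray level for pixels leaving the frame under rotation.
#' @return A `p x p x 4n` array (rotations of image `i` are consecutive).
#' @export
rotate_augment <- function(images, fill = 0.5) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  d <- dim(images)
  if (d[1] != d[2]) stop("`rotate_augment` requires square patches")
  n <- d[3]
  out <- array(fill, c(d[1], d[2], 4L * n))
  for (i in seq_len(n)) {
    for (k in 0:3) {
      out[, , 4L * (i - 1L) + k + 1L] <-
        rotate_image(images[, , i], 45 * k, fill)
    }
  }
  prov <- attr(images, "provenance")
  out <- with_provenance(out, "rotate_augment",
                         list(parent = if (is.null(prov)) NA else prov$id))
  out
}
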