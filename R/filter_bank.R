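#' Oriented quadrature filter banks for pairs of model V1 neurons
#'
#' Each model neuron is described by 18 band-pass filters sharing one
#' orientation: 9 receptive-field positions (one center, eight surround
#' positions spaced 45 degrees apart on a ring) times two phases (even/odd)
#' forming a quadrature pair, in the style of one band of a steerable
#' pyramid decomposition. Two such filter sets define a neuron pair and map
#' an image patch to a 36-dimensional observation vector.
#'
#' Conventions: orientations are degrees counterclockwise from horizontal
#' (a 0-degree filter responds maximally to a horizontal grating); image
#' matrices are row-major with the origin at the top-left, and the vertical
#' axis is flipped internally so that geometry follows standard mathematical
#' (y up) coordinates. Positions are expressed in RF-diameter units and
#' converted to pixels via `rf_diam_px`. Filters are ordered phase-major
#' within a neuron: filters 1-9 are even phase (center, then the eight
#' surround positions counterclockwise starting rightward), filters 10-18
#' the odd phases in the same position order; neuron 2 occupies 19-36.
#'
#' @name filter_bank
NULL

.kernel_params <- function(rf_diam_px, scale = 1L) {
  period <- (rf_diam_px / 2) * 2^(scale - 1L)
  list(period = period, sigma = period / 2, radius = 2 * period)
}

#' Render one oriented quadrature kernel
#'
#' @param orientation degrees counterclockwise from horizontal in `[0, 180)`.
#' @param phase `"even"` (cosine) or `"odd"` (sine carrier).
#' @param patch_px side length of the square patch, pixels.
#' @param center_px kernel center `(x, y)` in pixel coordinates (x rightward,
#'   y downward, 1-based); defaults to the patch center.
#' @param rf_diam_px receptive-field diameter in pixels; the carrier period
#'   is `rf_diam_px / 2` and the kernel support radius twice the period.
#' @param scale spatial-frequency band index; band `s` doubles the period
#'   `s - 1` times.
#' @return A `patch_px x patch_px` matrix with exactly zero mean and unit
#'   L2 norm; support is truncated at twice the carrier period.
#' @export
filter_kernel <- function(orientation, phase = c("even", "odd"), patch_px,
                          center_px = NULL, rf_diam_px = 16, scale = 1L) {
  phase <- match.arg(phase)
  kp <- .kernel_params(rf_diam_px, scale)
  if (is.null(center_px)) center_px <- c((patch_px + 1) / 2, (patch_px + 1) / 2)
  xs <- seq_len(patch_px) - center_px[1]          # x, rightward
  ys <- -(seq_len(patch_px) - center_px[2])       # y, upward (rows go down)
  X <- matrix(xs, patch_px, patch_px, byrow = TRUE)
  Y <- matrix(ys, patch_px, patch_px)
  th <- orientation * pi / 180
  u <- -X * sin(th) + Y * cos(th)                 # carrier axis, perp. to stripes
  r2 <- X^2 + Y^2
  env <- exp(-r2 / (2 * kp$sigma^2)) * (r2 <= kp$radius^2)
  carrier <- if (phase == "even") cos(2 * pi * u / kp$period) else sin(2 * pi * u / kp$period)
  k <- carrier * env
  # exact zero mean, removed proportionally to the envelope to keep locality
  k <- k - (sum(k) / sum(env)) * env
  k / sqrt(sum(k^2))
}

.filter_set <- function(orientation, center_rf, surround_radius_rf) {
  ang <- (0:7) * 45 * pi / 180                     # CCW from rightward
  pos <- rbind(c(0, 0), cbind(cos(ang), sin(ang)) * surround_radius_rf)
  pos <- sweep(pos, 2, center_rf, "+")
  data.frame(
    orientation = orientation,
    phase = rep(c("even", "odd"), each = 9L),
    pos_x = rep(pos[, 1], 2L),
    pos_y = rep(pos[, 2], 2L),
    position = rep(seq_len(9L), 2L)
  )
}

#' Build the filter geometry of a model neuron pair
#'
#' The reference neuron is horizontal at the patch center; the second neuron
#' is rotated by `dtheta` and displaced by `(dx, dy)` receptive-field
#' diameters.
#'
#' @param dtheta orientation-preference difference, degrees in `[0, 90]`.
#' @param dx,dy receptive-field center offset of the second neuron in
#'   RF-diameter units, each in `[-3, 3]`.
#' @param scale spatial-frequency band index (>= 1).
#' @param surround_radius_rf distance of the eight surround positions from
#'   the RF center, in RF diameters. The default (1) places them abutting
#'   the center filter.
#' @return An object of class `pair_geometry`: a list with the two filter
#'   sets (18 rows each) and the geometry parameters.
#' @export
build_pair_geometry <- function(dtheta, dx = 0, dy = 0, scale = 1L,
                                surround_radius_rf = 1) {
  if (!is.finite(dtheta) || dtheta < 0 || dtheta > 90)
    stop("`dtheta` must lie in [0, 90] degrees; got ", dtheta)
  if (!is.finite(dx) || !is.finite(dy) || abs(dx) > 3 || abs(dy) > 3)
    stop("RF offsets must lie in [-3, 3] RF units; got dx = ", dx, ", dy = ", dy)
  if (scale < 1) stop("`scale` must be a band index >= 1")
  g <- list(
    sets = list(
      .filter_set(0, c(0, 0), surround_radius_rf),
      .filter_set(dtheta, c(dx, dy), surround_radius_rf)
    ),
    dtheta = dtheta, dx = dx, dy = dy, scale = as.integer(scale),
    surround_radius_rf = surround_radius_rf
  )
  class(g) <- "pair_geometry"
  g
}

#' @export
print.pair_geometry <- function(x, ...) {
  cat(sprintf(
    "pair_geometry: dtheta = %g deg, offset = (%g, %g) RF, scale %d, 36 filters\n",
    x$dtheta, x$dx, x$dy, x$scale))
  invisible(x)
}

#' Minimum patch size that contains all kernels of a geometry
#'
#' @param geometry a [build_pair_geometry()] object.
#' @param rf_diam_px receptive-field diameter in pixels.
#' @return Required square patch side, pixels.
#' @export
min_patch_px <- function(geometry, rf_diam_px = 16) {
  kp <- .kernel_params(rf_diam_px, geometry$scale)
  pos <- do.call(rbind, lapply(geometry$sets, function(s) cbind(s$pos_x, s$pos_y)))
  reach <- max(abs(pos)) * rf_diam_px + kp$radius
  as.integer(2 * ceiling(reach) + 2)
}

#' Render the filter matrix of a neuron pair
#'
#' @inheritParams min_patch_px
#' @param patch_px patch side, pixels; must be at least [min_patch_px()].
#' @return A `36 x patch_px^2` matrix; row `k` is filter `k` flattened in
#'   column-major order, so observation vectors are `F %*% as.vector(image)`.
#' @export
pair_filter_matrix <- function(geometry, patch_px, rf_diam_px = 16) {
  stopifnot(inherits(geometry, "pair_geometry"))
  need <- min_patch_px(geometry, rf_diam_px)
  if (patch_px < need)
    stop("image too small for this geometry: need at least ", need,
         " px, got ", patch_px)
  ctr <- (patch_px + 1) / 2
  specs <- do.call(rbind, geometry$sets)
  F <- matrix(0, nrow(specs), patch_px^2)
  for (k in seq_len(nrow(specs))) {
    cx <- ctr + specs$pos_x[k] * rf_diam_px
    cy <- ctr - specs$pos_y[k] * rf_diam_px       # y up -> row down
    F[k, ] <- as.vector(filter_kernel(specs$orientation[k], specs$phase[k],
                                      patch_px, c(cx, cy), rf_diam_px,
                                      geometry$scale))
  }
  F
}

#' Indices of the center-position quadrature filters of each neuron
#'
#' @param geometry a [build_pair_geometry()] object (used only for its size).
#' @return A list with `even` and `odd` integer vectors of length 2
#'   (neuron 1, neuron 2).
#' @export
center_indices <- function(geometry = NULL) {
  list(even = c(1L, 19L), odd = c(10L, 28L))
}

#' Map images to 36-dimensional observation vectors
#'
#' Applies the 36 oriented filters of a pair geometry to one image or an
#' image stack by inner products. Filters have zero mean, so a constant
#' image maps to the zero vector.
#'
#' @param images a `p x p` matrix or a `p x p x n` array of gray images in
#'   `[0, 1]`.
#' @inheritParams pair_filter_matrix
#' @param filter_matrix optionally a precomputed [pair_filter_matrix()]
#'   (must match `patch` and `rf_diam_px`); avoids re-rendering kernels in
#'   loops.
#' @return An `n x 36` matrix of observation vectors (a single image gives
#'   `n = 1`); the stack's `provenance` attribute, if any, is carried over.
#' @export
apply_filters <- function(images, geometry, rf_diam_px = 16,
                          filter_matrix = NULL) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  d <- dim(images)
  if (length(d) != 3L || d[1] != d[2])
    stop("`images` must be a square matrix or a p x p x n array")
  if (is.null(filter_matrix))
    filter_matrix <- pair_filter_matrix(geometry, d[1], rf_diam_px)
  else if (ncol(filter_matrix) != d[1]^2)
    stop("`filter_matrix` was rendered for a different patch size")
  x <- t(filter_matrix %*% matrix(images, d[1] * d[2], d[3]))
  colnames(x) <- paste0("x", seq_len(ncol(x)))
  attr(x, "provenance") <- attr(images, "provenance")
  x
}

#' Window an image in a circular aperture on a gray backdrop
#'
#' @param image a `p x p` gray image in `[0, 1]`.
#' @param diameter_deg aperture diameter, degrees of visual angle.
#' @param pixels_per_degree pixels per degree of visual angle.
#' @param background gray level outside the aperture (mean luminance).
#' @return The image with all pixels farther than `diameter_deg / 2` from
#'   the patch center replaced by `background`. Idempotent.
#' @export
window_image <- function(image, diameter_deg, pixels_per_degree,
                         background = 0.5) {
  if (diameter_deg <= 0) stop("`diameter_deg` must be positive")
  p <- nrow(image)
  rad_px <- diameter_deg * pixels_per_degree / 2
  if (2 * rad_px > p)
    stop("aperture (", 2 * rad_px, " px) larger than the image (", p, " px)")
  ctr <- (p + 1) / 2
  xs <- seq_len(p) - ctr
  r2 <- outer(xs^2, xs^2, "+")
  image[r2 > rad_px^2] <- background
  image
}

#' Quadrature orientation energy of an image stack
#'
#' Mean (even^2 + odd^2) response of a centered quadrature pair per
#' orientation, a phase-invariant measure of oriented energy used to check
#' orientation balance of image ensembles.
#'
#' @param images a `p x p x n` image stack.
#' @param orientations degrees, default the four 45-degree steps.
#' @param rf_diam_px receptive-field diameter in pixels.
#' @return Named numeric vector of mean energies per orientation.
#' @export
orientation_energy <- function(images, orientations = c(0, 45, 90, 135),
                               rf_diam_px = 16) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  p <- dim(images)[1]
  M <- matrix(images, p * p, dim(images)[3])
  out <- vapply(orientations, function(th) {
    ke <- as.vector(filter_kernel(th, "even", p, rf_diam_px = rf_diam_px))
    ko <- as.vector(filter_kernel(th, "odd", p, rf_diam_px = rf_diam_px))
    mean((ke %*% M)^2 + (ko %*% M)^2)
  }, numeric(1))
  names(out) <- paste0("deg", orientations)
  out
}
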