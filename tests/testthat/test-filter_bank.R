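test_that("pair geometry construction validates its inputs", {
  expect_error(build_pair_geometry(100, 0, 0), "0, 90")
  expect_error(build_pair_geometry(-5, 0, 0), "0, 90")
  expect_error(build_pair_geometry(40, 4, 0), "-3, 3")
  expect_error(build_pair_geometry(40, 0, -3.5), "-3, 3")
  g <- build_pair_geometry(90, 2.25, 0)
  expect_s3_class(g, "pair_geometry")
  expect_equal(g$dtheta, 90)
  g2 <- build_pair_geometry(40, 0, 0)
  expect_equal(nrow(g2$sets[[1]]), 18L)
})

test_that("identical geometry gives two identical filter sets", {
  g <- build_pair_geometry(0, 0, 0)
  expect_identical(g$sets[[1]], g$sets[[2]])
  Fm <- pair_filter_matrix(g, min_patch_px(g, 8), 8)
  expect_equal(Fm[1:18, ], Fm[19:36, ])
})

test_that("filters have zero mean, unit norm, and map images to 36 dims", {
  g <- build_pair_geometry(40, 0.75, -0.5)
  p <- min_patch_px(g, 8)
  Fm <- pair_filter_matrix(g, p, 8)
  expect_equal(dim(Fm), c(36L, p^2))
  expect_lt(max(abs(rowSums(Fm))), 1e-10)            # zero mean
  expect_equal(unname(rowSums(Fm^2)), rep(1, 36))    # unit energy
  x <- apply_filters(matrix(0.5, p, p), g, 8)
  expect_equal(ncol(x), 36L)
  expect_lt(max(abs(x)), 1e-12)                      # constant image -> 0
})

test_that("filter response to its own kernel equals the squared norm", {
  g <- build_pair_geometry(30, 0, 0)
  p <- min_patch_px(g, 8)
  Fm <- pair_filter_matrix(g, p, 8)
  img <- matrix(Fm[5, ], p, p)
  x <- apply_filters(img, g, 8, filter_matrix = Fm)
  # independent oracle: direct elementwise summation
  brute <- sum(matrix(Fm[5, ], p, p) * img)
  expect_equal(unname(x[1, 5]), brute, tolerance = 1e-12)
  expect_equal(unname(x[1, 5]), sum(Fm[5, ]^2), tolerance = 1e-12)
})

test_that("images smaller than the kernel span are rejected with the minimum", {
  g <- build_pair_geometry(0, 2.25, 0)
  need <- min_patch_px(g, 16)
  expect_error(apply_filters(matrix(0.5, 32, 32), g, 16),
               as.character(need))
})

test_that("even/odd kernels are a quadrature pair (phase-invariant energy)", {
  p <- 96; period <- 8
  en <- vapply(seq(0, 2 * pi, length.out = 16), function(ph) {
    I <- matrix(rep(0.5 + 0.4 * cos(2 * pi * (1:p) / period + ph), times = p), p, p)
    ke <- filter_kernel(0, "even", p, rf_diam_px = 16)
    ko <- filter_kernel(0, "odd", p, rf_diam_px = 16)
    sum(ke * I)^2 + sum(ko * I)^2
  }, numeric(1))
  expect_lt((max(en) - min(en)) / mean(en), 0.01)
})

test_that("filters are translation-equivariant for integer pixel shifts", {
  p <- 96; rf <- 8
  set.seed(5)
  img <- matrix(runif(p * p), p, p)
  g0 <- build_pair_geometry(0, 0, 0)
  g1 <- build_pair_geometry(0, 1, 0)    # second neuron shifted +1 RF (8 px)
  x_off <- apply_filters(img, g1, rf)
  shifted <- img
  shifted[, 1:(p - rf)] <- img[, (rf + 1):p]   # shift content left by 8 px
  x_ctr <- apply_filters(shifted, g0, rf)
  # neuron 2 filters of the offset geometry on the original image equal
  # centered filters on the shifted image (away from the border)
  expect_equal(unname(x_off[1, 19:36]), unname(x_ctr[1, 1:18]),
               tolerance = 1e-10)
})

test_that("grating energy decreases monotonically with orientation difference", {
  p <- 96; period <- 8
  eng <- vapply(c(0, 22.5, 45, 67.5, 90), function(dt) {
    ke <- filter_kernel(dt, "even", p, rf_diam_px = 16)
    ko <- filter_kernel(dt, "odd", p, rf_diam_px = 16)
    mean(vapply(seq(0, 2 * pi, length.out = 8), function(ph) {
      I <- matrix(rep(0.5 + 0.4 * cos(2 * pi * (1:p) / period + ph), times = p), p, p)
      sum(ke * I)^2 + sum(ko * I)^2
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(eng) < 0))
})

test_that("windowing replaces pixels outside the aperture and is idempotent", {
  p <- 64
  img <- matrix(runif(p * p), p, p)
  w <- window_image(img, 1.0, 16, background = 0.5)
  ctr <- (p + 1) / 2
  expect_equal(w[1, 1], 0.5)
  expect_equal(w[round(ctr), round(ctr)], img[round(ctr), round(ctr)])
  # pixel just beyond the 8 px radius is background
  expect_equal(w[round(ctr), round(ctr) + 9], 0.5)
  expect_equal(window_image(w, 1.0, 16), w)
  # the small/large diameters used throughout are accepted
  expect_silent(window_image(img, 1.0, 8))
  expect_silent(window_image(img, 6.7, 8))
  expect_error(window_image(img, 10, 16), "larger than the image")
})
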