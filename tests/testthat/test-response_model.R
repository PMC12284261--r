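test_that("the complex-cell response rectifies and scales feature samples", {
  # one neuron's center pair lives at columns (1, 2) when m = 2
  g <- rbind(c(2, -1, 0.3, 0.1))
  r <- samples_to_rates(g, response_config(alpha = 1, offset = 0))
  expect_equal(unname(r[1, 1]), 2)                     # max(2,0) + max(-1,0)
  g2 <- rbind(c(1.5, 0.5, 0, 0))
  r2 <- samples_to_rates(g2, response_config(alpha = 2, offset = 0))
  expect_equal(unname(r2[1, 1]), 4)
  g3 <- rbind(c(-1, -2, 0, 0))
  r3 <- samples_to_rates(g3, response_config(alpha = 1, offset = 0))
  expect_equal(unname(r3[1, 1]), 0)                    # full rectification
  expect_true(all(samples_to_rates(matrix(rnorm(40), 10, 4)) >= 0))
  ri <- samples_to_rates(g2, response_config(alpha = 1, offset = 0,
                                             round_to_counts = TRUE))
  expect_true(all(ri == round(ri)))
  expect_error(response_config(alpha = 0), "positive")
  expect_error(samples_to_rates(g, center = list(even = c(1, 9), odd = c(2, 10))),
               "out of range")
})

test_that("spike-count correlation behaves like a Pearson coefficient", {
  expect_equal(rsc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rsc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(rsc(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)  # hand computation
  expect_error(rsc(1:3, 1:4), "equal length")
  expect_error(rsc(1:2, 1:2), "at least 3")
  expect_warning(r0 <- rsc(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r0))
  # symmetry and invariance to positive affine rescaling
  set.seed(71)
  a <- rnorm(50); b <- 0.4 * a + rnorm(50)
  expect_equal(rsc(a, b), rsc(b, a))
  expect_equal(rsc(2 * a + 5, b), rsc(a, b))
})

test_that("expected rates match sampled response means", {
  ps <- toy_shared()
  x <- gen_gsm_observations(ps, 1, seed = 72)$x[1, ]
  er <- expected_rates(matrix(x, 1), ps, response_config(), n_grid = 128)
  post <- sample_posterior(x, ps, n_samples = 8000, chains = 4,
                           warmup = 300, seed = 11)
  r <- samples_to_rates(post$g)
  se <- apply(r, 2, sd) / sqrt(min(post$diagnostics$ess[1:4]))
  expect_true(all(abs(colMeans(r) - er[1, ]) < 4 * se + 1e-6))
  # independent structure path
  pi2 <- toy_independent()
  xi <- gen_gsm_observations(pi2, 1, seed = 73)$x[1, ]
  eri <- expected_rates(matrix(xi, 1), pi2, n_grid = 24)
  posti <- sample_posterior(xi, pi2, n_samples = 6000, chains = 4,
                            warmup = 300, seed = 12)
  ri <- samples_to_rates(posti$g)
  sei <- apply(ri, 2, sd) / sqrt(min(posti$diagnostics$ess[1:4]))
  expect_true(all(abs(colMeans(ri) - eri[1, ]) < 4 * sei + 1e-6))
})

test_that("identical model neurons have unit signal correlation", {
  tr <- trained_fixture()
  g0 <- build_pair_geometry(0, 0, 0)
  p0 <- suppressWarnings(
    train_pair_gsm(tr$natural, tr$noise, g0, "shared", rf_diam_px = tr$rf))
  probes <- stim_fixture()[, , 1:12]
  rs <- model_signal_correlation(g0, p0, probes, rf_diam_px = tr$rf,
                                 n_grid = 48)
  expect_equal(rs, 1, tolerance = 1e-6)
  expect_error(model_signal_correlation(g0, p0, probes[, , 1, drop = FALSE],
                                        rf_diam_px = tr$rf), "at least 2")
})

test_that("probe selection keeps the strongest drivers of the reference filter", {
  tr <- trained_fixture()
  pool <- stim_fixture()
  sel <- select_probe_images(pool, tr$geom_shared, 10, tr$rf)
  expect_equal(dim(sel)[3], 10L)
  ci <- center_indices()
  energy <- function(stack) {
    x <- apply_filters(stack, tr$geom_shared, tr$rf)
    mean(x[, ci$even[1]]^2 + x[, ci$odd[1]]^2)
  }
  expect_gt(energy(sel), energy(pool))
})

test_that("pair simulation returns correlations per size deterministically", {
  tr <- trained_fixture()
  img <- stim_fixture()[, , 3]
  a <- simulate_pair(img, tr$geom_shared, tr$shared, rf_diam_px = tr$rf,
                     n_samples = 300, chains = 2, warmup = 100, seed = 13)
  b <- simulate_pair(img, tr$geom_shared, tr$shared, rf_diam_px = tr$rf,
                     n_samples = 300, chains = 2, warmup = 100, seed = 13)
  expect_identical(a$rsc, b$rsc)
  expect_true(all(abs(a$rsc) <= 1))
  expect_equal(a$modulation, unname(a$rsc["small"] - a$rsc["large"]))
  expect_named(a$rsc, c("small", "large"))
  # fixed-modulator variant runs and reports the conditioning value
  f <- simulate_pair(img, tr$geom_shared, tr$shared, rf_diam_px = tr$rf,
                     n_samples = 300, seed = 13, marginalize = FALSE)
  expect_true(is.numeric(f$diagnostics$small$fixed_modulator))
})

test_that("modulation sign is stable across rectification offsets", {
  # reuse one posterior per stimulus and size, with common feature
  # innovations across sizes; the offset only affects the response
  # nonlinearity
  tr <- trained_fixture()
  stim <- stim_fixture()
  Fm <- pair_filter_matrix(tr$geom_shared, tr$patch, tr$rf)
  mods <- sapply(1:24, function(i) {
    set.seed(500 + i)
    Z <- matrix(rnorm(2000 * 36), 2000, 36)
    g_by_size <- lapply(c(1, 4), function(sz) {
      img <- window_image(stim[, , i], sz, tr$rf)
      x <- as.vector(apply_filters(img, tr$geom_shared, tr$rf, Fm))
      sample_posterior(x, tr$shared, 2000, 2, 200, seed = 500 + i,
                       g_innovations = Z)$g
    })
    vapply(c(0, 0.5, 1), function(off) {
      r <- lapply(g_by_size, samples_to_rates,
                  config = response_config(offset = off))
      suppressWarnings(rsc(r[[1]][, 1], r[[1]][, 2]) -
                         rsc(r[[2]][, 1], r[[2]][, 2]))
    }, numeric(1))
  })
  m <- rowMeans(mods, na.rm = TRUE)
  expect_equal(sign(m[1]), sign(m[2]))
  expect_equal(sign(m[2]), sign(m[3]))
})
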