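test_that("white-noise images hit the target mean and SD and are reproducible", {
  x <- gen_white_noise_images(2000, 32, seed = 4)
  expect_true(all(x >= 0 & x <= 1))
  expect_lt(abs(mean(x) - 0.5), 0.01)
  expect_lt(abs(sd(x) - 0.1), 0.01)
  y <- gen_white_noise_images(2000, 32, seed = 4)
  expect_identical(x, y)
  one <- gen_white_noise_images(1, 16, seed = 1)
  expect_equal(dim(one), c(16L, 16L, 1L))
  expect_true(all(one >= 0 & one <= 1))
  expect_error(gen_white_noise_images(0, 16))
  expect_false(is.null(attr(x, "provenance")))
})

test_that("single-region surrogates have leptokurtic filter outputs", {
  cfg <- surrogate_image_config(size = 48, layout = "single", seed = 9)
  imgs <- gen_surrogate_images(cfg, 1000)
  g <- build_pair_geometry(0, 0, 0)
  x <- apply_filters(imgs, g, 8)
  kurt <- mean(x[, 1]^4) / mean(x[, 1]^2)^2
  expect_gt(kurt, 3.3)
})

test_that("split-region surrogates give uncorrelated left/right contrasts", {
  cfg <- surrogate_image_config(size = 64, layout = "split", seed = 10)
  imgs <- gen_surrogate_images(cfg, 1000)
  # energy of single oriented filters centered in each half
  p <- 64
  kl <- as.vector(filter_kernel(0, "even", p, c(16, 32.5), 8))
  kr <- as.vector(filter_kernel(0, "even", p, c(48, 32.5), 8))
  M <- matrix(imgs, p * p, 1000)
  el <- as.vector(kl %*% M)^2
  er <- as.vector(kr %*% M)^2
  expect_lt(abs(cor(el, er)), 0.1)
  # sanity: within one region the same texture drives both phases
  cm <- attr(imgs, "contrast")
  expect_false(isTRUE(all.equal(cm[, 1], cm[, 2])))
})

test_that("constant contrast multiplier gives Gaussian filter statistics", {
  cfg <- surrogate_image_config(size = 48, layout = "single",
                                contrast_shape = Inf, contrast_scale = 1,
                                seed = 11)
  imgs <- gen_surrogate_images(cfg, 1000)
  expect_true(all(attr(imgs, "contrast") == 1))
  x <- apply_filters(imgs, build_pair_geometry(0, 0, 0), 8)
  kurt <- mean(x[, 1]^4) / mean(x[, 1]^2)^2
  expect_lt(abs(kurt - 3), 0.45)
})

test_that("rotation augmentation quadruples the stack and respects symmetry", {
  set.seed(3)
  imgs <- gen_surrogate_images(surrogate_image_config(size = 32, seed = 3), 5)
  aug <- rotate_augment(imgs)
  expect_equal(dim(aug)[3], 20L)
  expect_equal(aug[, , 1], imgs[, , 1])  # 0-degree copy
  expect_error(rotate_augment(array(0.5, c(16, 18, 2))), "square")
  # rotationally symmetric disk is invariant
  p <- 33; ctr <- 17
  r2 <- outer((1:p - ctr)^2, (1:p - ctr)^2, "+")
  disk <- 0.5 + 0.3 * (r2 <= 64)
  da <- rotate_augment(array(disk, c(p, p, 1)))
  for (k in 2:4)
    expect_lt(mean(abs(da[, , k] - disk)), 0.02)  # bilinear blur at the rim
})

test_that("augmentation flattens the orientation-energy histogram", {
  cfg <- surrogate_image_config(size = 64, texture = "oriented",
                                texture_orientation = 0, seed = 12)
  imgs <- gen_surrogate_images(cfg, 40)
  e0 <- orientation_energy(imgs, rf_diam_px = 8)
  e1 <- orientation_energy(rotate_augment(imgs), rf_diam_px = 8)
  expect_gt(max(e0) / min(e0), max(e1) / min(e1))
})

test_that("forward GSM draws have the covariance the model implies", {
  ps <- toy_shared()
  obs <- gen_gsm_observations(ps, 50000, seed = 21)
  # E[x x'] = E[v^2] Sigma_g + Sigma_noise with E[v^2] = 2
  target <- 2 * ps$Sigma_g + ps$Sigma_noise
  relerr <- norm(cov(obs$x) - target, "F") / norm(target, "F")
  expect_lt(relerr, 0.05)
  # noiseless draws divided by the recorded modulator are exactly Gaussian
  p0 <- gsm_params("shared", ps$Sigma_g, diag(4) * 0)
  o0 <- gen_gsm_observations(p0, 50000, seed = 22)
  g_rec <- o0$x / as.vector(o0$v)
  expect_lt(norm(cov(g_rec) - ps$Sigma_g, "F") / norm(ps$Sigma_g, "F"), 0.05)
  # second-moment error shrinks roughly like 1/sqrt(n)
  e_at <- function(n) {
    o <- gen_gsm_observations(ps, n, seed = 23)
    norm(cov(o$x) - target, "F")
  }
  expect_lt(e_at(40000), e_at(2500))
})

test_that("independent forward draws with block-diagonal noise decorrelate neurons", {
  pi2 <- toy_independent()
  Sn_bd <- pi2$Sigma_noise
  Sn_bd[1:2, 3:4] <- 0; Sn_bd[3:4, 1:2] <- 0
  p_bd <- gsm_params("independent", pi2$Sigma_g, Sn_bd)
  obs <- gen_gsm_observations(p_bd, 50000, seed = 24)
  cross <- cov(obs$x)[1:2, 3:4]
  expect_lt(max(abs(cross)), 4 * sqrt(8 / 50000))  # within MC error of 0
})

test_that("copula calibration hits planted count correlations", {
  set.seed(31); n <- 2e5
  for (case in list(c(0.15, 2.5, 2.5), c(-0.1, 1.2, 3))) {
    rho <- poisson_copula_rho(case[1], case[2], case[3])
    z <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, rho, rho, 1), 2))
    cnt <- cbind(qpois(pnorm(z[, 1]), case[2]), qpois(pnorm(z[, 2]), case[3]))
    expect_lt(abs(cor(cnt[, 1], cnt[, 2]) - case[1]), 0.01)
  }
  expect_equal(poisson_copula_rho(0, 2, 2), 0)
  expect_error(poisson_copula_rho(0.9, 0.05, 0.05), "bound")
})

test_that("synthetic sessions respect their configuration", {
  fx <- session_fixture()
  ds <- fx$dataset
  expect_s3_class(ds, "recording_dataset")
  expect_equal(dim(ds$counts), c(20L, 80L, 2L, 20L))
  # marginal mean counts track the configured profiles
  cc <- which(fx$labels == "centered")
  m_small <- mean(ds$counts[cc, , "small", ])
  expect_lt(abs(m_small / 2.5 - 1), 0.25)   # lognormal gain dispersion
  # determinism
  ds2 <- gen_synthetic_session(fx$config)
  expect_identical(ds$counts, ds2$counts)
  # no off-centered neurons requested -> only centered pairs
  cfg0 <- synthetic_session_config(n_centered = 6L, n_offcentered = 0L,
                                   n_images = 10L, n_trials = 10L, seed = 2L)
  pt0 <- build_pair_table(gen_synthetic_session(cfg0))
  expect_true(all(pt0$class == "centered"))
})

test_that("null sessions carry no planted correlation", {
  cfg <- synthetic_session_config(
    n_centered = 10L, n_offcentered = 0L, n_images = 60L, n_trials = 25L,
    rsc = list(centered = c(small = 0, large = 0),
               mixed = c(small = 0, large = 0),
               offcentered = c(small = 0, large = 0)),
    seed = 5L)
  pt <- build_pair_table(gen_synthetic_session(cfg))
  m <- mean(c(pt$r_small, pt$r_large), na.rm = TRUE)
  expect_lt(abs(m), 0.01)
})

test_that("infeasible correlation targets are rejected by name", {
  cfg <- synthetic_session_config(
    rsc = list(centered = c(small = 0.95, large = 0.1),
               mixed = c(small = 0, large = 0),
               offcentered = c(small = 0, large = 0)),
    rates = list(centered = c(small = 0.05, large = 1),
                 offcentered = c(small = 0.05, large = 1)),
    n_images = 2L, seed = 1L)
  expect_error(gen_synthetic_session(cfg), "bound|infeasible")
})
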