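test_that("conditional posterior matches hand-derived linear-Gaussian algebra", {
  # 2-dim toy: Sigma_g = I, Sigma_noise = I, v = 1, x = (2, 0)
  p2 <- gsm_params("shared", diag(2), diag(2))
  cp <- conditional_posterior(c(2, 0), p2, 1)
  expect_equal(cp$mean, c(1, 0))
  expect_equal(cp$cov, diag(2) / 2)
  # x = 0: mean 0, covariance independent of x
  cp0 <- conditional_posterior(c(0, 0), p2, 1)
  expect_equal(cp0$mean, c(0, 0))
  expect_equal(cp0$cov, cp$cov)
  # noiseless limit: v = 2, x = 2 * 1 => g = x / v = 1, vanishing covariance
  pn <- gsm_params("shared", diag(2), diag(2) * 1e-12)
  cpn <- conditional_posterior(c(2, 2), pn, 2)
  expect_equal(cpn$mean, c(1, 1), tolerance = 1e-6)
  expect_lt(max(abs(cpn$cov)), 1e-6)
  expect_error(conditional_posterior(c(1, 1), p2, c(1, 2)), "1 positive")
  expect_error(conditional_posterior(c(1, 1), p2, -1), "positive")
})

test_that("quadrature oracle is normalized, stable, and degenerates correctly", {
  ps <- toy_shared()
  x <- gen_gsm_observations(ps, 1, seed = 51)$x[1, ]
  o64 <- posterior_oracle(x, ps, n_grid = 64)
  o128 <- posterior_oracle(x, ps, n_grid = 128)
  expect_equal(sum(o128$weights), 1, tolerance = 1e-12)
  expect_lt(max(abs(o64$mean - o128$mean)) / max(abs(o128$mean)), 1e-3)
  expect_lt(max(abs(o64$cov - o128$cov)) / max(abs(o128$cov)), 1e-3)
  # single grid point reduces exactly to the conditional posterior
  cp <- conditional_posterior(x, ps, 1.3)
  od <- posterior_oracle(x, ps, grid = 1.3)
  expect_equal(od$mean, cp$mean)
  expect_equal(od$cov, cp$cov)
  # independent structure likewise
  pi2 <- toy_independent()
  xi <- gen_gsm_observations(pi2, 1, seed = 52)$x[1, ]
  oi <- posterior_oracle(xi, pi2, n_grid = 40, q_tail = 1e-9)
  expect_equal(sum(oi$weights), 1, tolerance = 1e-12)
  cpi <- conditional_posterior(xi, pi2, c(1.1, 0.7))
  odi <- posterior_oracle(xi, pi2, grid = 1.1)
  expect_equal(dim(odi$weights), c(1L, 1L))
})

test_that("the tail audit rejects grids that truncate the modulator posterior", {
  ps <- toy_shared()
  x <- rep(20, 4)   # extreme observation pushes mass to the upper boundary
  expect_error(posterior_oracle(x, ps, n_grid = 32), "extend the grid")
})

test_that("collapsed sampler is seed-deterministic with positive modulators", {
  ps <- toy_shared()
  x <- gen_gsm_observations(ps, 1, seed = 53)$x[1, ]
  a <- sample_posterior(x, ps, n_samples = 200, chains = 2, warmup = 50, seed = 9)
  b <- sample_posterior(x, ps, n_samples = 200, chains = 2, warmup = 50, seed = 9)
  expect_identical(a$g, b$g)
  expect_identical(a$v, b$v)
  expect_true(all(a$v > 0))
  expect_equal(nrow(a$g), 200L)
  expect_named(a$diagnostics, c("rhat", "ess", "flagged"))
  expect_true(all(is.finite(a$diagnostics$rhat)))
  expect_error(sample_posterior(x, ps, n_samples = 7, chains = 2), "multiple")
})

test_that("sampler moments agree with the oracle within Monte-Carlo error", {
  for (par in list(toy_shared(), toy_independent())) {
    x <- gen_gsm_observations(par, 1, seed = 54)$x[1, ]
    o <- posterior_oracle(x, par, q_tail = 1e-9,
                          n_grid = if (par$structure == "shared") 128 else 48)
    post <- sample_posterior(x, par, n_samples = 4000, chains = 4,
                             warmup = 300, seed = 10)
    se <- posterior_mc_se(post)[1:4]
    expect_true(all(abs(colMeans(post$g) - o$mean) < 3 * se + 1e-8))
    expect_lt(max(abs(cov(post$g) - o$cov)) / max(diag(o$cov)), 0.12)
  }
})

test_that("marginal likelihood matches closed forms and integrates to one", {
  # degenerate prior at v = 1 in 1-D: standard normal log-density
  p1 <- gsm_params("shared", matrix(0.5), matrix(0.5))
  expect_equal(marginal_loglik(0, p1, grid = 1), -0.5 * log(2 * pi),
               tolerance = 1e-9)
  # identical shared/independent models with degenerate priors: zero ratio
  Sg <- diag(c(0.8, 1.1)); Sn <- matrix(c(0.4, 0.1, 0.1, 0.3), 2)
  psh <- gsm_params("shared", Sg, Sn)
  pin <- gsm_params("independent", Sg, Sn)
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(marginal_loglik(X, psh, grid = 1),
               marginal_loglik(X, pin, grid = 1), tolerance = 1e-12)
  # 1-D quadrature against an independent brute-force trapezoid over (v, x)
  pm <- gsm_params("shared", matrix(0.7), matrix(0.3))
  vg <- seq(1e-5, 9, length.out = 300000)
  brute <- vapply(c(0, 0.5, 2), function(x0)
    log(sum(dweibull(vg, 2, sqrt(2)) *
              dnorm(x0, 0, sqrt(vg^2 * 0.7 + 0.3))) * (vg[2] - vg[1])),
    numeric(1))
  ours <- marginal_loglik(matrix(c(0, 0.5, 2), ncol = 1), pm,
                          n_grid = 8192, q_tail = 1e-9)
  expect_lt(max(abs(ours - brute)), 1e-5)
  # the 1-D marginal integrates to 1 over x
  xs <- seq(-12, 12, length.out = 1201)
  Z <- sum(exp(marginal_loglik(matrix(xs, ncol = 1), pm, tail_tol = Inf))) *
    (xs[2] - xs[1])
  expect_lt(abs(Z - 1), 1e-2)
})

test_that("log-likelihood ratio is an exact difference with consistent sign", {
  ps <- toy_shared()
  # an independent-structure sibling sharing the within-neuron blocks
  Sg_i <- ps$Sigma_g; Sg_i[1:2, 3:4] <- 0; Sg_i[3:4, 1:2] <- 0
  pin <- gsm_params("independent", Sg_i, ps$Sigma_noise)
  te <- gen_gsm_observations(ps, 400, seed = 55)
  lr <- loglik_ratio(te$x, ps, pin, n_grid = 64, q_tail = 1e-9)
  expect_equal(lr$ratio, lr$loglik_shared - lr$loglik_independent)
  expect_gt(mean(lr$ratio), 0)    # shared data favor the shared model
  expect_error(loglik_ratio(te$x, pin, ps), "shared-structure")
})

test_that("marginalization changes the feature posterior beyond any fixed modulator", {
  ps <- toy_shared()
  # a strongly driven observation, where modulator uncertainty matters
  x <- 3 * gen_gsm_observations(ps, 1, seed = 56)$x[1, ]
  o <- posterior_oracle(x, ps, q_tail = 1e-10)
  vhat <- modulator_mode(x, ps)
  cp <- conditional_posterior(x, ps, vhat)
  corr_of <- function(C) C[1, 3] / sqrt(C[1, 1] * C[3, 3])
  # the marginalized posterior carries extra correlated (modulator-driven)
  # uncertainty that no fixed-v conditional reproduces
  expect_gt(abs(corr_of(o$cov) - corr_of(cp$cov)), 0.02)
  expect_gt(sum(diag(o$cov)), 1.05 * sum(diag(cp$cov)))
})

test_that("ratio maps demand held-out test images and a trained grid", {
  tr <- trained_fixture()
  grid1 <- data.frame(dtheta = 40, dx = 0, dy = 0)
  expect_error(
    loglik_ratio_map(tr$natural, grid1, tr$natural, tr$noise, rf_diam_px = tr$rf),
    "provenance")
  expect_equal(nrow(default_geometry_grid()), 9L * 81L)
})
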