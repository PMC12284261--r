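make_tiny_dataset <- function(counts, rf, baseline_mean, baseline_sd,
                              platform = "planar_array") {
  out <- list(counts = counts, rf = rf, stim_center = c(0, 0),
              diameters = c(small = 1, large = 6.7),
              baseline = data.frame(neuron = seq_len(dim(counts)[1]),
                                    mean = baseline_mean, sd = baseline_sd),
              platform = platform, config = NULL)
  class(out) <- "recording_dataset"
  out
}

test_that("neurons classify by RF distance with a gap between thresholds", {
  rf <- data.frame(neuron = 1:4, x_deg = c(0.5, 1.1, 1.5, 5),
                   y_deg = c(0, 0, 0, 0))
  counts <- array(1L, c(4, 2, 2, 5), dimnames = list(NULL, NULL,
                                                     c("small", "large"), NULL))
  ds <- make_tiny_dataset(counts, rf, 0.2, 0.1)
  lab <- classify_neurons(ds)
  expect_equal(as.character(lab),
               c("centered", "excluded", "offcentered", "excluded"))
  # raising the centered threshold never removes a centered label
  lab2 <- classify_neurons(ds, centered_thresh = 1.2)
  expect_true(all(which(lab == "centered") %in% which(lab2 == "centered")))
  # missing RF centers are excluded
  rf$x_deg[1] <- NA
  ds2 <- make_tiny_dataset(counts, rf, 0.2, 0.1)
  expect_message(lab3 <- classify_neurons(ds2), "without RF")
  expect_equal(as.character(lab3)[1], "excluded")
})

test_that("responsivity thresholds follow the platform rules", {
  rf <- data.frame(neuron = 1:3, x_deg = c(0.2, 0.3, 1.5), y_deg = 0)
  counts <- array(0L, c(3, 1, 2, 10), dimnames = list(NULL, NULL,
                                                      c("small", "large"), NULL))
  # neuron 1 centered, evoked(small) = 1.6 > max(1.0 + 0.5, 0.1): included
  counts[1, 1, "small", ] <- c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 2L, 1L, 1L)
  # neuron 2 centered, evoked(small) = 0.05: below the 0.1 floor, excluded
  counts[2, 1, "small", ] <- c(rep(0L, 9L), 0L)
  # neuron 3 off-centered responsive at both sizes: excluded
  counts[3, 1, "small", ] <- 3L
  counts[3, 1, "large", ] <- 3L
  ds <- make_tiny_dataset(counts, rf, c(1.0, 0, 0.2), c(0.5, 0.02, 0.1))
  expect_equal(responsivity_filter(ds, 1), 1L)
  # once the off-centered neuron stops responding to small stimuli it enters
  counts[3, 1, "small", ] <- 0L
  ds2 <- make_tiny_dataset(counts, rf, c(1.0, 0, 0.2), c(0.5, 0.02, 0.1))
  expect_setequal(responsivity_filter(ds2, 1), c(1L, 3L))
  # high-density probes use the softer 0.1 SD criterion with a capped baseline
  ds3 <- make_tiny_dataset(counts, rf, c(1.0, 0, 0.2), c(0.5, 0.02, 0.1),
                           platform = "high_density_probe")
  thr <- pairgsm:::.responsivity_thresholds(ds3)
  expect_equal(thr, pmax(pmin(c(1.0, 0, 0.2), 0.1) + 0.1 * c(0.5, 0.02, 0.1),
                         0.1))
})

test_that("pair tables keep centered and mixed pairs only", {
  fx <- session_fixture()
  pt <- fx$pair_table
  expect_setequal(unique(pt$class), c("centered", "mixed"))
  # no off-centered pair may appear
  off <- which(fx$labels == "offcentered")
  expect_false(any(pt$n1 %in% off & pt$n2 %in% off))
  expect_true(all(abs(pt$r_small) <= 1, na.rm = TRUE))
  expect_true(all(pt$distance >= 0))
  # planted class means are recovered to reasonable precision
  agg <- aggregate(cbind(r_small, r_large) ~ class, pt, mean, na.rm = TRUE)
  planted <- fx$config$rsc
  cen <- agg[agg$class == "centered", ]
  expect_lt(abs(cen$r_small - planted$centered["small"]), 0.03)
  expect_lt(abs(cen$r_large - planted$centered["large"]), 0.03)
})

test_that("a neuron paired with its twin has unit signal correlation", {
  set.seed(81)
  counts <- array(rpois(2 * 30 * 2 * 8, 3), c(2, 30, 2, 8),
                  dimnames = list(NULL, NULL, c("small", "large"), NULL))
  counts[2, , , ] <- counts[1, , , ]
  rf <- data.frame(neuron = 1:2, x_deg = c(0.1, -0.1), y_deg = 0)
  ds <- make_tiny_dataset(counts, rf, 0, 0.01)
  pt <- build_pair_table(ds)
  expect_equal(unique(pt$r_signal), 1)
})

test_that("mean matching equalizes the count histograms exactly", {
  fx <- session_fixture()
  pt <- fx$pair_table[fx$pair_table$class == "centered", ]
  mm <- mean_matching(pt, n_boot = 50, seed = 3)
  expect_equal(mm$hist_means[["small"]], mm$hist_means[["large"]])
  expect_true(is.finite(mm$t_test$p.value))
  expect_equal(dim(mm$boot), c(50L, 2L))
  # identical count distributions: everything is retained and matched means
  # equal the raw means
  pt_id <- pt
  pt_id$mean_count_large <- pt_id$mean_count_small
  mm_id <- mean_matching(pt_id, n_boot = 5, seed = 4)
  expect_equal(mm_id$n_matched, nrow(pt_id))
  expect_equal(unname(mm_id$matched_mean["small"]), mean(pt_id$r_small))
  expect_equal(unname(mm_id$matched_mean["large"]), mean(pt_id$r_large))
  # disjoint histograms cannot be matched
  pt_dis <- pt
  pt_dis$mean_count_large <- pt_dis$mean_count_small + 1000
  expect_error(mean_matching(pt_dis), "disjoint")
})

test_that("factor analysis recovers planted dimensionality", {
  set.seed(82)
  n <- 200; p <- 10
  L <- matrix(rnorm(p), p, 1) * 1.5
  Y1 <- matrix(rnorm(n), n, 1) %*% t(L) + matrix(rnorm(n * p), n, p)
  expect_gte(fa_dimensionality(Y1, K_max = 4, folds = 4, seed = 1), 1L)
  Y0 <- matrix(rnorm(n * p), n, p)
  expect_lte(fa_dimensionality(Y0, K_max = 4, folds = 4, seed = 1), 1L)
  f1 <- fit_fa(Y1, 1)
  expect_equal(dim(f1$Lambda), c(p, 1L))
  expect_true(all(f1$Psi > 0))
  expect_gt(f1$loglik, fit_fa(Y1, 0)$loglik)
})

test_that("the subsampling rule draws M x K pairs per image", {
  fx <- session_fixture()
  pt <- fx$pair_table[fx$pair_table$class == "centered", ]
  pt1 <- pt[pt$image == pt$image[1], ]
  M <- length(responsivity_filter(fx$dataset, pt1$image[1], fx$labels))
  ss <- suppressWarnings(
    subsampled_significance(pt1, fx$dataset, fx$labels, n_repeats = 3,
                            K_fixed = 2L, seed = 2))
  expect_equal(unname(ss$K), 2L)
  # with K = 0 every image is skipped and no p-value can be formed
  ss0 <- subsampled_significance(pt1, fx$dataset, fx$labels, n_repeats = 3,
                                 K_fixed = 0L, seed = 2)
  expect_true(is.nan(ss0$p) || is.na(ss0$p))
  expect_equal(ss0$n_images, 0L)
})

test_that("binned modulation respects bin counts and degenerate input", {
  fx <- session_fixture()
  pt <- fx$pair_table
  bm <- binned_modulation(pt, n_rsignal_bins = 15, n_distance_bins = 20,
                          min_per_bin = 15)
  expect_lte(nrow(bm), 300L)
  expect_true(all(bm$n >= 15))
  # a single bin reproduces the overall mean
  one <- binned_modulation(pt, n_rsignal_bins = 1, n_distance_bins = 1,
                           min_per_bin = 1)
  cc <- complete.cases(pt[, c("r_small", "r_large", "r_signal", "distance")])
  expect_equal(one$modulation, mean(pt$r_small[cc] - pt$r_large[cc]))
  expect_error(binned_modulation(pt, min_per_bin = 1e6), "min_per_bin")
})

test_that("planted suppression/facilitation structure shows up in the map", {
  fx <- session_fixture()
  bm <- binned_modulation(fx$pair_table, n_rsignal_bins = 3,
                          n_distance_bins = 6, min_per_bin = 15)
  near <- bm[bm$distance < 1, ]
  far <- bm[bm$distance > 1.3, ]
  # centered pairs (close) were planted with suppression, mixed (far) with
  # facilitation
  expect_gt(mean(near$modulation > 0), 0.9)
  expect_gt(mean(far$modulation < 0), 0.9)
})

test_that("regression recovers a noiseless planted map exactly", {
  # orthogonal factorial design so variance shares are analytic
  des <- expand.grid(r_signal = seq(-1, 1, length.out = 5),
                     distance = seq(0, 2, length.out = 6))
  z <- function(x) (x - mean(x)) / sd(x)
  des$modulation <- 0.15 * z(des$r_signal) - 0.57 * z(des$distance)
  des$n <- 20L
  reg <- modulation_regression(des)
  expect_equal(unname(reg$coefficients["z_rsignal", 1]), 0.15, tolerance = 1e-10)
  expect_equal(unname(reg$coefficients["z_distance", 1]), -0.57, tolerance = 1e-10)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  share <- c(0.15^2, 0.57^2) / (0.15^2 + 0.57^2)
  expect_equal(unname(reg$delta_r2["r_signal"]), share[1], tolerance = 1e-10)
  expect_equal(unname(reg$delta_r2["distance"]), share[2], tolerance = 1e-10)
  expect_error(modulation_regression(des[1:2, ]), "at least 3")
})

test_that("pure-noise maps yield near-zero regression structure", {
  set.seed(83)
  cover <- replicate(40, {
    des <- expand.grid(r_signal = seq(-1, 1, length.out = 5),
                       distance = seq(0, 2, length.out = 6))
    des$modulation <- rnorm(nrow(des), 0, 0.05)
    reg <- modulation_regression(des)
    abs(reg$coefficients["z_distance", 1]) <
      3 * reg$coefficients["z_distance", 2]
  })
  expect_gt(mean(cover), 0.9)
  }
)
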