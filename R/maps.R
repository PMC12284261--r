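#' Model-comparison and prediction maps over pair geometries
#'
#' Drivers that sweep grids of pair geometries (orientation difference and
#' RF offset), train a shared- and an independent-modulator GSM per
#' geometry, and tabulate (i) which structure better captures the image
#' statistics (mean log-likelihood ratio on held-out images) and (ii) the
#' predicted surround modulation of pairwise correlations under the better
#' structure, binned by model signal correlation and RF distance.
#'
#' @name model_maps
NULL

#' Default geometry grid
#'
#' 81 RF offsets (a 9 x 9 grid spanning -3 to 3 RF in both directions) for
#' each of 9 orientation differences (10 to 90 degrees).
#'
#' @export
default_geometry_grid <- function() {
  expand.grid(dtheta = seq(10, 90, by = 10),
              dx = seq(-3, 3, by = 0.75),
              dy = seq(-3, 3, by = 0.75))
}

#' Log-likelihood ratio map over pair geometries
#'
#' For each geometry the shared and independent GSMs are trained by moment
#' matching on the training ensembles, and the per-image log marginal
#' likelihood ratio (shared minus independent) is evaluated on the test
#' images, which are first brought to the training contrast scale (the
#' same signal-to-noise rescaling the training ensemble received; the
#' filters are linear, so the observation vectors are simply multiplied by
#' the training scalar). Training and test stacks must be disjoint, which
#' is enforced by comparing their provenance stamps.
#'
#' @param test_images `p x p x n` stack of held-out images.
#' @param geometry_grid data frame with columns `dtheta`, `dx`, `dy` (see
#'   [default_geometry_grid()]).
#' @param natural_train,noise_train training stacks.
#' @param rf_diam_px RF diameter, pixels.
#' @param snr_target,cross_set_scale training options (see
#'   [train_pair_gsm()]).
#' @param n_grid_shared,n_grid_indep quadrature resolutions.
#' @param q_tail_shared,q_tail_indep prior tail probability excluded by the
#'   modulator grids; the defaults are wider than [v_grid()]'s because test
#'   ensembles routinely contain images whose modulator posterior reaches
#'   past the central prior mass.
#' @return List with `map` (per-geometry mean ratio and its standard
#'   error) and `per_image` (long table of per-image ratios).
#' @export
loglik_ratio_map <- function(test_images, geometry_grid,
                             natural_train, noise_train,
                             rf_diam_px = 16, snr_target = 4.8,
                             cross_set_scale = 1,
                             n_grid_shared = 128L, n_grid_indep = 48L,
                             q_tail_shared = 1e-9, q_tail_indep = 1e-12) {
  id_test <- provenance_id(test_images)
  if (!is.null(id_test) &&
      (identical(id_test, provenance_id(natural_train)) ||
         identical(id_test, provenance_id(noise_train))))
    stop("test images share provenance with a training stack; ",
         "likelihood ratios must be computed on held-out images")
  rows <- vector("list", nrow(geometry_grid))
  per_image <- vector("list", nrow(geometry_grid))
  for (k in seq_len(nrow(geometry_grid))) {
    gg <- geometry_grid[k, ]
    geom <- build_pair_geometry(gg$dtheta, gg$dx, gg$dy)
    shared <- train_pair_gsm(natural_train, noise_train, geom, "shared",
                             snr_target, cross_set_scale,
                             rf_diam_px = rf_diam_px)
    indep <- train_pair_gsm(natural_train, noise_train, geom, "independent",
                            snr_target, cross_set_scale,
                            rf_diam_px = rf_diam_px)
    x <- attr(shared, "snr_scalar") *
      apply_filters(test_images, geom, rf_diam_px)
    lr_s <- marginal_loglik(x, shared, n_grid = n_grid_shared,
                            q_tail = q_tail_shared)
    lr_i <- marginal_loglik(x, indep, n_grid = n_grid_indep,
                            q_tail = q_tail_indep)
    ratio <- lr_s - lr_i
    rows[[k]] <- data.frame(gg, mean_ratio = mean(ratio),
                            se_ratio = stats::sd(ratio) / sqrt(length(ratio)))
    per_image[[k]] <- data.frame(gg, image = seq_along(ratio), ratio = ratio,
                                 row.names = NULL)
  }
  list(map = do.call(rbind, rows), per_image = do.call(rbind, per_image))
}

#' Model-side map of surround modulation of correlations
#'
#' For each geometry instance: train both structures, pick the better one
#' by the sign of the mean log-likelihood ratio on the evaluation images,
#' measure the model signal correlation over probe images, then simulate
#' the pair at the two sizes for each stimulus image and record the
#' correlation modulation. Evaluation, probe and stimulus images are all
#' brought to the training contrast scale first. Instances are finally
#' binned by signal
#' correlation and RF distance; each bin reports the selected structure
#' (by its mean ratio) and mean modulation.
#'
#' @param geometry_grid data frame of `dtheta`, `dx`, `dy`.
#' @param natural_train,noise_train training stacks.
#' @param eval_images held-out stack for the likelihood ratio.
#' @param stim_images stack of stimulus images for the pair simulations.
#' @param probe_images stack for signal correlations (see
#'   [select_probe_images()]).
#' @param rf_diam_px RF diameter, pixels.
#' @param sizes aperture diameters, degrees (RF = 1 degree).
#' @param response a [response_config()].
#' @param n_samples,chains,warmup,seed sampler settings per simulation.
#' @param n_rsignal_bins,n_distance_bins,min_per_bin binning controls.
#' @param n_grid_indep quadrature resolution for independent-model terms.
#' @param q_tail_shared,q_tail_indep modulator-grid tail probabilities for
#'   the likelihood-ratio evaluation (wide, as in [loglik_ratio_map()]).
#' @return List with `instances` (geometry x image rows) and `map`
#'   (binned structure and mean modulation).
#' @export
model_modulation_map <- function(geometry_grid, natural_train, noise_train,
                                 eval_images, stim_images, probe_images,
                                 rf_diam_px = 16,
                                 sizes = c(small = 1, large = 4),
                                 response = response_config(),
                                 n_samples = 400L, chains = 2L,
                                 warmup = 200L, seed = 1L,
                                 n_rsignal_bins = 3L, n_distance_bins = 3L,
                                 min_per_bin = 10L, n_grid_indep = 32L,
                                 q_tail_shared = 1e-9, q_tail_indep = 1e-12) {
  inst <- vector("list", nrow(geometry_grid))
  n_stim <- dim(stim_images)[3]
  for (k in seq_len(nrow(geometry_grid))) {
    gg <- geometry_grid[k, ]
    geom <- build_pair_geometry(gg$dtheta, gg$dx, gg$dy)
    shared <- train_pair_gsm(natural_train, noise_train, geom, "shared",
                             rf_diam_px = rf_diam_px)
    indep <- train_pair_gsm(natural_train, noise_train, geom, "independent",
                            rf_diam_px = rf_diam_px)
    # evaluation, probe and stimulus images all enter at the training
    # contrast scale, matching how the models were fit
    s_tr <- attr(shared, "snr_scalar")
    xe <- s_tr * apply_filters(eval_images, geom, rf_diam_px)
    ratio <- mean(marginal_loglik(xe, shared, q_tail = q_tail_shared) -
                    marginal_loglik(xe, indep, n_grid = n_grid_indep,
                                    q_tail = q_tail_indep))
    best <- if (ratio > 0) shared else indep
    rs <- model_signal_correlation(geom, best,
                                   0.5 + s_tr * (probe_images - 0.5),
                                   rf_diam_px, response)
    Fm <- pair_filter_matrix(geom, dim(stim_images)[1], rf_diam_px)
    mods <- vapply(seq_len(n_stim), function(i) {
      simulate_pair(0.5 + s_tr * (stim_images[, , i] - 0.5), geom, best,
                    sizes, rf_diam_px,
                    response = response, n_samples = n_samples,
                    chains = chains, warmup = warmup,
                    seed = seed + 101L * k + i,
                    filter_matrix = Fm)$modulation
    }, numeric(1))
    inst[[k]] <- data.frame(gg, image = seq_len(n_stim),
                            distance = sqrt(gg$dx^2 + gg$dy^2),
                            r_signal = rs, mean_ratio = ratio,
                            structure = if (ratio > 0) "shared" else "independent",
                            modulation = mods, row.names = NULL)
  }
  instances <- do.call(rbind, inst)
  eq_edges <- function(x, k) {
    e <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1L)))
    e[1] <- e[1] - 1e-9; e[length(e)] <- e[length(e)] + 1e-9
    e
  }
  bs <- cut(instances$r_signal,
            eq_edges(instances$r_signal, n_rsignal_bins), labels = FALSE)
  bd <- cut(instances$distance,
            eq_edges(instances$distance, n_distance_bins), labels = FALSE)
  key <- interaction(bs, bd, drop = TRUE)
  map <- data.frame(
    r_signal_bin = tapply(bs, key, "[", 1),
    distance_bin = tapply(bd, key, "[", 1),
    r_signal = tapply(instances$r_signal, key, mean),
    distance = tapply(instances$distance, key, mean),
    mean_ratio = tapply(instances$mean_ratio, key, mean),
    modulation = tapply(instances$modulation, key, mean),
    n = as.vector(table(key)))
  map$structure <- ifelse(map$mean_ratio > 0, "shared", "independent")
  map <- map[map$n >= min_per_bin, ]
  rownames(map) <- NULL
  list(instances = instances, map = map)
}
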