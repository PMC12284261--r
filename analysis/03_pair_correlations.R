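#!/usr/bin/env Rscript
# Surround modulation of model pair correlations: sample the marginalized
# posterior for surrogate stimuli windowed at a small (center-only) and a
# large (center + surround) aperture, convert samples to complex-cell
# responses, and compare r_sc between sizes for (a) the shared model with
# overlapping filters and (b) the independent model with offset filters.
# Also repeats the shared condition with the modulator fixed (no
# marginalization) to show the modulation disappears.
library(pairgsm)

seed <- 1L
rf <- 8; patch <- 96; n_stim <- 150L
dir.create("results", showWarnings = FALSE)

# ensembles at the source experiments' size; the heavy-tailed prior
# covariance needs the large natural ensemble to stabilize
noise <- gen_white_noise_images(2000, patch, seed = seed)
natural <- gen_surrogate_images(
  surrogate_image_config(size = patch, layout = "single", seed = seed + 1L),
  10000)
gS <- build_pair_geometry(40, 0, 0)
gI <- build_pair_geometry(0, 2.25, 0)
fit_geom <- function(geom, structure) {
  xw <- apply_filters(noise, geom, rf)
  xn <- apply_filters(natural, geom, rf)
  suppressWarnings(train_pair_gsm_obs(xn, xw, structure))
}
pS <- fit_geom(gS, "shared")
pI <- fit_geom(gI, "independent")
rm(natural); invisible(gc(FALSE))
stim <- gen_surrogate_images(
  surrogate_image_config(size = patch, layout = "single", seed = seed + 32L), n_stim)
stim <- 0.5 + attr(pS, "snr_scalar") * (stim - 0.5)

run <- function(geom, par, tag, marginalize = TRUE) {
  Fm <- pair_filter_matrix(geom, patch, rf)
  out <- lapply(seq_len(n_stim), function(i) {
    sp <- simulate_pair(stim[, , i], geom, par, rf_diam_px = rf,
                        n_samples = 2000, chains = 4, warmup = 200,
                        seed = seed + 1000L + i, marginalize = marginalize,
                        filter_matrix = Fm)
    data.frame(condition = tag, image = i, rsc_small = sp$rsc["small"],
               rsc_large = sp$rsc["large"], modulation = sp$modulation)
  })
  do.call(rbind, out)
}
tab <- rbind(run(gS, pS, "shared_overlapping"),
             run(gI, pI, "independent_offset"),
             run(gS, pS, "shared_fixed_modulator", marginalize = FALSE))
rownames(tab) <- NULL
write.csv(tab, "results/pair_correlations.csv", row.names = FALSE)

summ <- do.call(rbind, lapply(split(tab, tab$condition), function(d) {
  dd <- d$modulation[is.finite(d$modulation)]   # clipped cases excluded
  tt <- t.test(dd)
  data.frame(condition = d$condition[1],
             mean_rsc_small = mean(d$rsc_small, na.rm = TRUE),
             mean_rsc_large = mean(d$rsc_large, na.rm = TRUE),
             mean_modulation = mean(dd),
             p_paired = tt$p.value, n = length(dd))
}))
write.csv(summ, "results/pair_correlations_summary.csv", row.names = FALSE)
write_manifest("results", list(stage = "pair_correlations", n_stim = n_stim), seed)
cat("Surround modulation of model correlations (small minus large):\n")
print(summ, row.names = FALSE)
cat("\nExpected: suppression (positive modulation) for the shared model,",
    "facilitation (negative) for the independent model, and a collapse of",
    "the shared modulation once the modulator is fixed.\n")
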