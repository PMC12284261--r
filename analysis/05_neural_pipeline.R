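#!/usr/bin/env Rscript
# The spike-count data pipeline on a planted synthetic multi-session
# dataset: classification, responsivity, pair tables, mean-matching,
# factor-analysis subsampled significance, binned modulation and the
# final regression on tuning similarity and RF distance.
library(pairgsm)

seed <- 1L
dir.create("results", showWarnings = FALSE)

sessions <- lapply(1:2, function(k)
  gen_synthetic_session(synthetic_session_config(n_images = 270L,
                                                 seed = seed + k)))
tabs <- lapply(sessions, function(ds) {
  lab <- classify_neurons(ds)
  cbind(session = match(list(ds), sessions), build_pair_table(ds, lab))
})
pt <- do.call(rbind, Map(function(t, k) transform(t, session = k),
                         tabs, seq_along(tabs)))
write.csv(pt[sample.int(nrow(pt), min(nrow(pt), 5000)), ],
          "results/pair_table_sample.csv", row.names = FALSE)

rows <- list(); fa_rows <- list()
for (cl in c("centered", "mixed")) {
  d <- pt[pt$class == cl, ]
  mm <- mean_matching(d, n_boot = 500, seed = seed)
  rows[[cl]] <- data.frame(
    class = cl, raw_small = mean(d$r_small, na.rm = TRUE),
    raw_large = mean(d$r_large, na.rm = TRUE),
    matched_small = mm$matched_mean["small"],
    matched_large = mm$matched_mean["large"],
    p_meanmatched = mm$t_test$p.value, n_matched = mm$n_matched)
}
for (k in seq_along(sessions)) {
  lab <- classify_neurons(sessions[[k]])
  d <- tabs[[k]][tabs[[k]]$class == "centered", ]
  ss <- suppressWarnings(
    subsampled_significance(d, sessions[[k]], lab, n_repeats = 200,
                            K_max = 5, folds = 3, seed = seed + k))
  fa_rows[[k]] <- data.frame(session = k, p_subsampled = ss$p,
                             mean_difference = ss$mean_difference,
                             images_used = ss$n_images)
}
mm_tab <- do.call(rbind, rows); fa_tab <- do.call(rbind, fa_rows)
write.csv(mm_tab, "results/mean_matching.csv", row.names = FALSE)
write.csv(fa_tab, "results/subsampled_significance.csv", row.names = FALSE)

bm <- binned_modulation(pt, n_rsignal_bins = 10, n_distance_bins = 10,
                        min_per_bin = 15)
reg <- modulation_regression(bm)
write.csv(bm, "results/binned_modulation.csv", row.names = FALSE)
write.csv(data.frame(term = rownames(reg$coefficients),
                     reg$coefficients, check.names = FALSE),
          "results/modulation_regression.csv", row.names = FALSE)
write_manifest("results", list(stage = "neural_pipeline", sessions = 2L), seed)

cat("Mean-matched class means (small vs large):\n"); print(mm_tab, row.names = FALSE)
cat("\nFA-subsampled significance per session:\n"); print(fa_tab, row.names = FALSE)
cat(sprintf("\nBinned regression: R^2 = %.3f; delta-R^2 r_signal = %.3f, distance = %.3f\n",
            reg$r_squared, reg$delta_r2["r_signal"], reg$delta_r2["distance"]))
cat("Expected: centered suppression and mixed facilitation both survive",
    "mean-matching; distance dominates the binned regression.\n")
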