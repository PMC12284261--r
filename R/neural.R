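#' Spike-count data pipeline for surround modulation of correlations
#'
#' The data-side analyses: classify neurons by receptive-field position
#' relative to the stimulus, filter by per-image responsivity, build the
#' pair-by-image table of spike-count correlations at the two sizes,
#' control for firing-rate confounds by mean-matching, assess significance
#' with factor-analysis-guided pair subsampling, and relate the surround
#' modulation of correlations to tuning similarity and RF distance with a
#' binned regression.
#'
#' @name neural_analysis
NULL

#' Classify neurons by receptive-field position
#'
#' Centered: RF center within `centered_thresh` (default 1 degree) of the
#' stimulus center. Off-centered: farther than `offcentered_thresh`
#' (default 1.2 degrees) but covered by the large stimulus. Neurons in the
#' gap between the thresholds, outside the large stimulus, or without an
#' RF estimate are excluded.
#'
#' @param dataset a `recording_dataset`.
#' @param centered_thresh,offcentered_thresh degrees.
#' @return Factor of `"centered"`, `"offcentered"`, `"excluded"` per
#'   neuron; RF distances attached as attribute `distance`.
#' @export
classify_neurons <- function(dataset, centered_thresh = 1.0,
                             offcentered_thresh = 1.2) {
  rf <- dataset$rf
  dist <- sqrt((rf$x_deg - dataset$stim_center[1])^2 +
                 (rf$y_deg - dataset$stim_center[2])^2)
  lab <- rep("excluded", nrow(rf))
  lab[!is.na(dist) & dist < centered_thresh] <- "centered"
  covered <- !is.na(dist) & dist < dataset$diameters[["large"]] / 2
  lab[!is.na(dist) & dist > offcentered_thresh & covered] <- "offcentered"
  if (anyNA(dist))
    message(sum(is.na(dist)), " neuron(s) without RF center excluded")
  lab <- factor(lab, levels = c("centered", "offcentered", "excluded"))
  attr(lab, "distance") <- dist
  lab
}

.responsivity_thresholds <- function(dataset) {
  b <- dataset$baseline
  if (dataset$platform == "high_density_probe")
    pmax(pmin(b$mean, 0.1) + 0.1 * b$sd, 0.1)
  else
    pmax(b$mean + b$sd, 0.1)
}

#' Per-image responsive neuron set
#'
#' A centered neuron is included for an image when its small-size evoked
#' mean count exceeds the responsivity threshold (one baseline SD above
#' the spontaneous mean, and at least 0.1 spikes/trial; for high-density
#' probe recordings 0.1 SD above a baseline mean capped at 0.1). An
#' off-centered neuron must pass at the large size and *fail* at the small
#' size, ensuring the small stimulus does not encroach on its RF.
#'
#' @param dataset a `recording_dataset`.
#' @param image image index.
#' @param labels output of [classify_neurons()] (computed if missing).
#' @return Integer vector of included neuron indices.
#' @export
responsivity_filter <- function(dataset, image, labels = NULL) {
  if (is.null(labels)) labels <- classify_neurons(dataset)
  thr <- .responsivity_thresholds(dataset)
  ev_small <- rowMeans(dataset$counts[, image, "small", , drop = FALSE])
  ev_large <- rowMeans(dataset$counts[, image, "large", , drop = FALSE])
  keep <- (labels == "centered" & ev_small > thr) |
    (labels == "offcentered" & ev_large > thr & ev_small <= thr)
  which(keep)
}

# all-pairs Pearson correlation across trials; NA where undefined
.pair_cor <- function(counts_nt) {
  if (ncol(counts_nt) < 3L) return(matrix(NA_real_, nrow(counts_nt), nrow(counts_nt)))
  sds <- apply(counts_nt, 1, stats::sd)
  C <- suppressWarnings(stats::cor(t(counts_nt)))
  C[sds == 0, ] <- NA_real_
  C[, sds == 0] <- NA_real_
  C
}

#' Build the pair-by-image correlation table
#'
#' For every image, forms all pairs among the neurons passing the
#' responsivity filter, keeps centered-centered (`centered` class) and
#' centered-off-centered (`mixed`) pairs (off-centered pairs are not
#' analyzed: the small stimulus does not drive them), and records the
#' Pearson spike-count correlation across trials at each size, the pair's
#' signal correlation (correlation of across-image mean responses at the
#' large size), RF distance, and pair-averaged mean counts per size.
#' Cases with fewer than 3 trials or zero response variance carry `NA`
#' correlations.
#'
#' @param dataset a `recording_dataset`.
#' @param labels optional [classify_neurons()] output.
#' @return A data frame with one row per (pair, image).
#' @export
build_pair_table <- function(dataset, labels = NULL) {
  if (is.null(labels)) labels <- classify_neurons(dataset)
  cnt <- dataset$counts
  n_img <- dim(cnt)[2]
  mean_small <- apply(cnt[, , "small", , drop = FALSE], c(1, 2), mean)
  mean_large <- apply(cnt[, , "large", , drop = FALSE], c(1, 2), mean)
  sig_cor <- suppressWarnings(stats::cor(t(mean_large)))
  rfd <- as.matrix(stats::dist(dataset$rf[, c("x_deg", "y_deg")]))
  rows <- vector("list", n_img)
  for (t in seq_len(n_img)) {
    inc <- responsivity_filter(dataset, t, labels)
    if (length(inc) < 2L) next
    cs <- .pair_cor(cnt[, t, "small", ])
    cl <- .pair_cor(cnt[, t, "large", ])
    pr <- utils::combn(inc, 2L)
    l1 <- as.character(labels[pr[1, ]]); l2 <- as.character(labels[pr[2, ]])
    cls <- ifelse(l1 == "centered" & l2 == "centered", "centered",
                  ifelse(xor(l1 == "centered", l2 == "centered") &
                           l1 != "excluded" & l2 != "excluded",
                         "mixed", "drop"))
    keep <- cls != "drop"
    if (!any(keep)) next
    i <- pr[1, keep]; j <- pr[2, keep]
    rows[[t]] <- data.frame(
      image = t, n1 = i, n2 = j, class = cls[keep],
      r_small = cs[cbind(i, j)], r_large = cl[cbind(i, j)],
      r_signal = sig_cor[cbind(i, j)], distance = rfd[cbind(i, j)],
      mean_count_small = (mean_small[i, t] + mean_small[j, t]) / 2,
      mean_count_large = (mean_large[i, t] + mean_large[j, t]) / 2)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(image = integer(), n1 = integer(), n2 = integer(),
                      class = character(), r_small = numeric(),
                      r_large = numeric(), r_signal = numeric(),
                      distance = numeric(), mean_count_small = numeric(),
                      mean_count_large = numeric())
  rownames(out) <- NULL
  out
}

#' Mean-matching control for rate-driven correlation differences
#'
#' Builds histograms of the pair-averaged mean counts across cases
#' (pair x image), separately for the small and the large size, over
#' common equal-width bins; retains the common histogram (the per-bin
#' minimum of the two counts) by randomly subsampling cases on each side,
#' so the matched histograms are identical and their means agree exactly.
#' Mean correlations are recomputed on the retained cases, retained cases
#' are paired within bins, and a paired two-sided t-test compares sizes. A
#' bootstrap over the subsampling gives the distribution of matched mean
#' correlations.
#'
#' @param pair_table a [build_pair_table()] data frame (optionally
#'   filtered to one pair class).
#' @param n_boot bootstrap repetitions.
#' @param n_bins histogram bins over the pooled count range.
#' @param seed integer seed.
#' @return List with `matched_mean` (named small/large), `t_test`,
#'   `boot` (`n_boot x 2` matrix), `hist_means` (the matched histograms'
#'   means, equal by construction), and `n_matched`.
#' @export
mean_matching <- function(pair_table, n_boot = 1000L, n_bins = 20L,
                          seed = 1L) {
  pt <- pair_table[stats::complete.cases(
    pair_table[, c("r_small", "r_large", "mean_count_small",
                   "mean_count_large")]), ]
  if (nrow(pt) == 0L) stop("no complete cases to match")
  rng <- range(c(pt$mean_count_small, pt$mean_count_large))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  edges[1] <- edges[1] - 1e-9; edges[n_bins + 1L] <- edges[n_bins + 1L] + 1e-9
  bin_s <- cut(pt$mean_count_small, edges, labels = FALSE)
  bin_l <- cut(pt$mean_count_large, edges, labels = FALSE)
  common <- pmin(tabulate(bin_s, n_bins), tabulate(bin_l, n_bins))
  if (sum(common) == 0L)
    stop("count histograms for the two sizes are disjoint; matching impossible")
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  hist_means <- c(small = sum(common * mids) / sum(common),
                  large = sum(common * mids) / sum(common))
  draw_match <- function() {
    sel_s <- integer(0); sel_l <- integer(0)
    for (b in which(common > 0L)) {
      cand_s <- which(bin_s == b); cand_l <- which(bin_l == b)
      sel_s <- c(sel_s, cand_s[sample.int(length(cand_s), common[b])])
      sel_l <- c(sel_l, cand_l[sample.int(length(cand_l), common[b])])
    }
    list(s = sel_s, l = sel_l)
  }
  set.seed(seed)
  m0 <- draw_match()
  rs <- pt$r_small[m0$s]; rl <- pt$r_large[m0$l]
  tt <- if (length(rs) >= 3L) stats::t.test(rs, rl, paired = TRUE) else NULL
  boot <- matrix(NA_real_, n_boot, 2,
                 dimnames = list(NULL, c("small", "large")))
  for (b in seq_len(n_boot)) {
    mb <- draw_match()
    boot[b, ] <- c(mean(pt$r_small[mb$s]), mean(pt$r_large[mb$l]))
  }
  list(matched_mean = c(small = mean(rs), large = mean(rl)),
       t_test = tt, boot = boot, hist_means = hist_means,
       n_matched = sum(common))
}

# ---- factor analysis --------------------------------------------------------

#' Fit a Gaussian factor-analysis model by expectation-maximization
#'
#' `x ~ N(mu, Lambda Lambda' + Psi)` with `Psi` diagonal; `K = 0` reduces
#' to an independent (diagonal) model.
#'
#' @param Y `n x p` matrix (observations x variables).
#' @param K number of factors.
#' @param n_iter,tol EM iterations and log-likelihood tolerance.
#' @return List with `Lambda`, `Psi`, `mu`, `loglik`.
#' @export
fit_fa <- function(Y, K, n_iter = 200L, tol = 1e-6) {
  n <- nrow(Y); p <- ncol(Y)
  mu <- colMeans(Y)
  S <- stats::cov(Y) * (n - 1) / n
  vfloor <- 1e-6 * mean(diag(S)) + 1e-12
  diag(S) <- pmax(diag(S), vfloor)
  ll_of <- function(Sig) {
    U <- .chol_jitter(Sig, warn = FALSE)
    -n / 2 * (p * log(2 * pi) + 2 * sum(log(diag(U))) +
                sum(diag(chol2inv(U) %*% S)))
  }
  if (K == 0L) {
    Psi <- pmax(diag(S), vfloor)
    return(list(Lambda = matrix(0, p, 0), Psi = Psi, mu = mu,
                loglik = ll_of(diag(Psi, p))))
  }
  e <- eigen(S, symmetric = TRUE)
  Lambda <- e$vectors[, seq_len(K), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(K)], vfloor)), K)
  Psi <- pmax(diag(S) - rowSums(Lambda^2), vfloor)
  ll_old <- -Inf
  for (it in seq_len(n_iter)) {
    # E-step moments via the Woodbury-free K x K solve
    PsiL <- Lambda / Psi
    Mk <- diag(K) + crossprod(Lambda, PsiL)
    Mki <- chol2inv(chol(Mk))
    beta <- Mki %*% t(PsiL)                 # K x p, E[z|x] = beta (x - mu)
    SB <- S %*% t(beta)                     # p x K
    Ezz <- Mki + beta %*% SB                # K x K
    Lambda <- SB %*% chol2inv(chol(Ezz))
    Psi <- pmax(diag(S) - rowSums(Lambda * SB), vfloor)
    ll <- ll_of(tcrossprod(Lambda) + diag(Psi, p))
    if (abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  list(Lambda = Lambda, Psi = Psi, mu = mu,
       loglik = ll_of(tcrossprod(Lambda) + diag(Psi, p)))
}

#' Cross-validated factor-analysis dimensionality
#'
#' Selects the number of factors maximizing the mean held-out Gaussian
#' log-likelihood over folds; the candidate range is capped by the
#' Ledermann bound.
#'
#' @param Y `n x p` matrix.
#' @param K_max largest candidate dimensionality.
#' @param folds cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @param n_iter,tol EM budget per candidate fit; the default is looser
#'   than [fit_fa()]'s since ranking candidates does not need a fully
#'   polished optimum.
#' @return The selected `K` (>= 0); per-candidate scores as attribute
#'   `cv_loglik`.
#' @export
fa_dimensionality <- function(Y, K_max = 10L, folds = 5L, seed = 1L,
                              n_iter = 60L, tol = 1e-5) {
  n <- nrow(Y); p <- ncol(Y)
  ledermann <- floor((2 * p + 1 - sqrt(8 * p + 1)) / 2)
  Ks <- 0:min(K_max, ledermann, p - 1L)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  score <- vapply(Ks, function(K) {
    tot <- 0
    for (f in seq_len(folds)) {
      tr <- Y[fold_id != f, , drop = FALSE]
      te <- Y[fold_id == f, , drop = FALSE]
      if (nrow(tr) < 4L || nrow(te) < 1L) return(-Inf)
      fit <- fit_fa(tr, K, n_iter, tol)
      Sig <- tcrossprod(fit$Lambda) + diag(fit$Psi, p)
      U <- .chol_jitter(Sig, warn = FALSE)
      z <- forwardsolve(t(U), t(te) - fit$mu)
      tot <- tot - 0.5 * (nrow(te) * (p * log(2 * pi) +
                                        2 * sum(log(diag(U)))) + sum(z^2))
    }
    tot / n
  }, numeric(1))
  K <- Ks[which.max(score)]
  attr(K, "cv_loglik") <- stats::setNames(score, paste0("K", Ks))
  K
}

#' Factor-analysis-guided subsampled significance test
#'
#' The entries of an estimated correlation matrix are not independent, so
#' a t-test over all pairs inflates significance. For each image the
#' included neurons' spike counts (both sizes, centered within size)
#' determine a factor-analysis dimensionality `K`; `M_image x K` pairs
#' are then sampled from the `M_image (M_image - 1) / 2` available ones
#' (capped with a warning when fewer exist; images with `K = 0` are
#' skipped). Sampled cases are aggregated across images and a two-sided
#' paired t-test compares correlations between sizes. The whole procedure
#' is repeated and the p-values averaged.
#'
#' @param pair_table a [build_pair_table()] data frame.
#' @param dataset the `recording_dataset` behind it.
#' @param labels optional [classify_neurons()] output.
#' @param n_repeats subsampling repetitions.
#' @param K_max,folds passed to [fa_dimensionality()].
#' @param K_fixed optional integer overriding the factor-analysis
#'   dimensionality for every image (used to study the pair-budget rule in
#'   isolation).
#' @param seed integer seed.
#' @return List with the averaged p-value `p`, the mean size difference
#'   over sampled cases `mean_difference`, per-image `K`, and the number
#'   of images used.
#' @export
subsampled_significance <- function(pair_table, dataset, labels = NULL,
                                    n_repeats = 1000L, K_max = 10L,
                                    folds = 5L, K_fixed = NULL, seed = 1L) {
  if (is.null(labels)) labels <- classify_neurons(dataset)
  pt <- pair_table[stats::complete.cases(pair_table[, c("r_small", "r_large")]), ]
  images <- sort(unique(pt$image))
  Kv <- integer(length(images)); names(Kv) <- images
  avail <- vector("list", length(images))
  capped <- FALSE
  for (k in seq_along(images)) {
    t <- images[k]
    inc <- responsivity_filter(dataset, t, labels)
    Ys <- t(dataset$counts[inc, t, "small", ])
    Yl <- t(dataset$counts[inc, t, "large", ])
    Y <- rbind(scale(Ys, scale = FALSE), scale(Yl, scale = FALSE))
    Kv[k] <- if (is.null(K_fixed)) fa_dimensionality(Y, K_max, folds, seed + t)
             else as.integer(K_fixed)
    rows <- which(pt$image == t)
    n_take <- length(inc) * Kv[k]
    if (n_take > length(rows)) capped <- TRUE
    avail[[k]] <- list(rows = rows, n_take = min(n_take, length(rows)))
  }
  if (capped)
    warning("M_image x K exceeded the available pairs for some images; capped")
  set.seed(seed)
  ps <- numeric(n_repeats)
  diffs <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    sel <- unlist(lapply(avail, function(a) {
      if (a$n_take == 0L) return(integer(0))
      a$rows[sample.int(length(a$rows), a$n_take)]
    }))
    if (length(sel) < 3L) { ps[r] <- NA_real_; next }
    tt <- stats::t.test(pt$r_small[sel], pt$r_large[sel], paired = TRUE)
    ps[r] <- tt$p.value
    diffs[r] <- mean(pt$r_small[sel] - pt$r_large[sel])
  }
  list(p = mean(ps, na.rm = TRUE), mean_difference = mean(diffs, na.rm = TRUE),
       K = Kv, n_images = sum(Kv > 0))
}

#' Bin surround modulation of correlations by tuning and distance
#'
#' Cases (pair x image) are binned by signal correlation and RF distance
#' using equal-count bin edges; per bin the mean of `r_small - r_large`
#' is reported, and bins with fewer than `min_per_bin` cases are dropped.
#'
#' @param pair_table a [build_pair_table()] data frame.
#' @param n_rsignal_bins,n_distance_bins bins per axis (defaults target
#'   ~300 candidate bins).
#' @param min_per_bin minimal cases per retained bin.
#' @return Data frame with bin indices, bin-mean predictors, `modulation`
#'   and `n`.
#' @export
binned_modulation <- function(pair_table, n_rsignal_bins = 15L,
                              n_distance_bins = 20L, min_per_bin = 15L) {
  pt <- pair_table[stats::complete.cases(
    pair_table[, c("r_small", "r_large", "r_signal", "distance")]), ]
  if (nrow(pt) == 0L) stop("no complete cases to bin")
  eq_edges <- function(x, k) {
    e <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1L)))
    e[1] <- e[1] - 1e-9; e[length(e)] <- e[length(e)] + 1e-9
    e
  }
  es <- eq_edges(pt$r_signal, n_rsignal_bins)
  ed <- eq_edges(pt$distance, n_distance_bins)
  bs <- cut(pt$r_signal, es, labels = FALSE)
  bd <- cut(pt$distance, ed, labels = FALSE)
  mod <- pt$r_small - pt$r_large
  key <- interaction(bs, bd, drop = TRUE)
  agg <- data.frame(
    r_signal_bin = tapply(bs, key, "[", 1),
    distance_bin = tapply(bd, key, "[", 1),
    r_signal = tapply(pt$r_signal, key, mean),
    distance = tapply(pt$distance, key, mean),
    modulation = tapply(mod, key, mean),
    n = as.vector(table(key)))
  agg <- agg[agg$n >= min_per_bin, ]
  if (nrow(agg) == 0L)
    stop("all bins fall below `min_per_bin`; nothing to report")
  rownames(agg) <- NULL
  agg
}

#' Regression of binned modulation on tuning similarity and distance
#'
#' Ordinary least squares of the bin-mean modulation on z-scored signal
#' correlation and z-scored RF distance, with the variance explained,
#' two-sided coefficient p-values, and the drop in R-squared when either
#' predictor is removed.
#'
#' @param binned a [binned_modulation()] data frame (>= 3 rows).
#' @return List with `coefficients` (matrix with estimates and p-values),
#'   `r_squared`, `delta_r2` (named by dropped predictor), the predictor
#'   `condition_number`, and the fitted `model`.
#' @export
modulation_regression <- function(binned) {
  if (nrow(binned) < 3L) stop("need at least 3 populated bins")
  z <- function(x) (x - mean(x)) / stats::sd(x)
  df <- data.frame(modulation = binned$modulation,
                   z_rsignal = z(binned$r_signal),
                   z_distance = z(binned$distance))
  fit <- stats::lm(modulation ~ z_rsignal + z_distance, data = df)
  r2 <- summary(fit)$r.squared
  r2_no_rs <- summary(stats::lm(modulation ~ z_distance, data = df))$r.squared
  r2_no_d <- summary(stats::lm(modulation ~ z_rsignal, data = df))$r.squared
  cn <- kappa(stats::model.matrix(fit), exact = TRUE)
  if (cn > 1e6)
    warning("near-collinear predictors (condition number ", signif(cn, 3), ")")
  list(coefficients = summary(fit)$coefficients,
       r_squared = r2,
       delta_r2 = c(r_signal = r2 - r2_no_rs, distance = r2 - r2_no_d),
       condition_number = cn,
       model = fit)
}
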