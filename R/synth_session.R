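#' Synthetic multi-session spike-count datasets
#'
#' Emulates a surround-modulation recording session: neurons with planted
#' receptive-field geometry (a centered group within 1 degree of the
#' stimulus center, an off-centered group beyond 1.2 degrees but inside the
#' large stimulus), size-dependent firing-rate profiles, per-image tuning
#' (so signal correlations exist and fall off with RF separation), and
#' planted pairwise spike-count correlations per pair class at each
#' stimulus size. Counts are drawn from a Gaussian copula with Poisson
#' margins; the latent correlation is calibrated numerically so the
#' realized Pearson count correlation hits the planted target.
#'
#' @name synthetic_session
NULL

#' Latent Gaussian correlation achieving a target Poisson count correlation
#'
#' For `X_i = F^{-1}_{Poisson(lambda_i)}(Phi(Z_i))` with `(Z_1, Z_2)`
#' standard bivariate normal with correlation `rho_z`, the count covariance
#' has the Hermite expansion `sum_k rho_z^k / k! a_k(lambda_1)
#' a_k(lambda_2)` with `a_k(lambda) = E[X He_k(Z)]`; the coefficients are
#' computed by Gauss-Hermite quadrature and the polynomial solved for
#' `rho_z`.
#'
#' @param target_r desired Pearson correlation of the counts, in (-1, 1).
#' @param lambda1,lambda2 Poisson means.
#' @param max_k expansion order.
#' @return The latent normal correlation.
#' @export
poisson_copula_rho <- function(target_r, lambda1, lambda2, max_k = 12L) {
  if (abs(target_r) >= 1) stop("`target_r` must lie in (-1, 1)")
  if (target_r == 0) return(0)
  # the count is a staircase sum_j 1[Z >= z_j] over its jump points, and
  # E[1[Z >= a] He_k(Z)] = He_{k-1}(a) phi(a) exactly, so each Hermite
  # coefficient is a finite sum over the jumps
  hermite_a <- function(lambda) {
    J <- max(stats::qpois(1 - 1e-14, lambda), 1L)
    zj <- stats::qnorm(stats::ppois(seq_len(J) - 1L, lambda))
    zj <- zj[is.finite(zj)]
    phi <- stats::dnorm(zj)
    He_prev <- rep(1, length(zj)); He <- zj      # He_0, He_1 at the jumps
    a <- numeric(max_k)
    a[1] <- sum(phi)                             # uses He_0
    for (k in 2:max_k) {
      a[k] <- sum(He * phi)                      # uses He_{k-1}
      He_next <- zj * He - (k - 1) * He_prev
      He_prev <- He; He <- He_next
    }
    a
  }
  a1 <- hermite_a(lambda1); a2 <- hermite_a(lambda2)
  coef <- a1 * a2 / factorial(seq_len(max_k))
  sd12 <- sqrt(lambda1 * lambda2)      # copula preserves Poisson margins
  fcorr <- function(r) sum(coef * r^seq_along(coef)) / sd12
  bound <- fcorr(sign(target_r) * 0.999)
  if ((target_r > 0 && target_r > bound) || (target_r < 0 && target_r < bound))
    stop("target correlation ", target_r, " infeasible for these rates; ",
         "attainable bound is ", signif(bound, 3))
  stats::uniroot(function(r) fcorr(r) - target_r, c(-0.999, 0.999),
                 tol = 1e-8)$root
}

#' Configuration of a synthetic recording session
#'
#' Defaults describe a typical planar-array session: ~20 trials of each of
#' a few hundred images at two sizes (1 and 6.7 degrees), centered pairs
#' whose correlations are suppressed by the large size and mixed pairs
#' whose correlations are facilitated.
#'
#' @param n_centered,n_offcentered neurons per RF group.
#' @param rf_dispersion radius (degrees) within which centered RF centers
#'   scatter; off-centered neurons are placed between 1.3 and 2.8 degrees.
#' @param n_images,n_trials images and repeats per image and size.
#' @param rsc planted Pearson spike-count correlations: a list with
#'   `centered`, `mixed`, `offcentered` entries, each `c(small=, large=)`.
#' @param rates mean spike counts per trial: list with `centered` and
#'   `offcentered` entries, each `c(small=, large=)`. The off-centered
#'   small-size rate defaults to near-baseline (those neurons are not
#'   driven by the small stimulus).
#' @param baseline_mean,baseline_sd spontaneous-count statistics.
#' @param signal_sd strength of per-image tuning (log-rate scale); creates
#'   signal correlations that decay with RF angular separation.
#' @param stim_diam stimulus diameters, degrees, `c(small=, large=)`.
#' @param platform `"planar_array"` or `"high_density_probe"` (affects
#'   responsivity thresholds downstream).
#' @param seed integer seed.
#' @export
synthetic_session_config <- function(n_centered = 16L, n_offcentered = 10L,
                                     rf_dispersion = 0.6,
                                     n_images = 60L, n_trials = 20L,
                                     rsc = list(centered = c(small = 0.15, large = 0.10),
                                                mixed = c(small = 0.04, large = 0.08),
                                                offcentered = c(small = 0.0, large = 0.05)),
                                     rates = list(centered = c(small = 2.5, large = 1.8),
                                                  offcentered = c(small = 0.05, large = 2.0)),
                                     baseline_mean = 0.3, baseline_sd = 0.25,
                                     signal_sd = 0.6,
                                     stim_diam = c(small = 1, large = 6.7),
                                     platform = c("planar_array", "high_density_probe"),
                                     seed = 1L) {
  for (cl in names(rsc))
    if (any(abs(rsc[[cl]]) >= 1)) stop("planted correlations must lie in (-1, 1)")
  for (cl in names(rates))
    if (any(rates[[cl]] < 0)) stop("rates must be >= 0")
  cfg <- list(n_centered = as.integer(n_centered),
              n_offcentered = as.integer(n_offcentered),
              rf_dispersion = rf_dispersion, n_images = as.integer(n_images),
              n_trials = as.integer(n_trials), rsc = rsc, rates = rates,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              signal_sd = signal_sd, stim_diam = stim_diam,
              platform = match.arg(platform), seed = as.integer(seed))
  class(cfg) <- "session_config"
  cfg
}

#' Generate a synthetic recording session
#'
#' @param config a [synthetic_session_config()].
#' @return A `recording_dataset`: list with `counts` (neuron x image x
#'   size x trial integer array), `rf` (data frame of RF centers, degrees),
#'   `stim_center`, `diameters`, `baseline` (per-neuron mean and SD of
#'   spontaneous counts), `platform`, and the generating `config`.
#' @export
gen_synthetic_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  nc <- config$n_centered; no <- config$n_offcentered
  N <- nc + no
  if (N < 2L) stop("need at least two neurons")
  cls <- rep(c("centered", "offcentered"), c(nc, no))

  # RF centers: centered inside the small stimulus, off-centered outside
  # the 1.2 degree boundary but inside the large stimulus
  ang <- stats::runif(N, 0, 2 * pi)
  rad <- c(sqrt(stats::runif(nc)) * min(config$rf_dispersion, 0.95),
           stats::runif(no, 1.3, min(2.8, config$stim_diam["large"] / 2 - 0.3)))
  rf <- data.frame(neuron = seq_len(N), x_deg = rad * cos(ang),
                   y_deg = rad * sin(ang))

  base_gain <- exp(stats::rnorm(N, 0, 0.25))
  # two-factor per-image tuning; loading direction follows RF polar angle so
  # nearby neurons are similarly tuned (non-zero, distance-graded r_signal)
  load <- config$signal_sd * cbind(cos(ang), sin(ang))
  sig <- matrix(stats::rnorm(2L * config$n_images), config$n_images, 2L)

  sizes <- c("small", "large")
  counts <- array(0L, c(N, config$n_images, 2L, config$n_trials),
                  dimnames = list(NULL, NULL, sizes, NULL))
  rate_of <- function(size) {
    prof <- ifelse(cls == "centered", config$rates$centered[size],
                   config$rates$offcentered[size])
    prof * base_gain
  }
  cc <- which(cls == "centered"); oo <- which(cls == "offcentered")
  pair_class <- matrix("offcentered", N, N)
  pair_class[cc, cc] <- "centered"
  pair_class[cc, oo] <- "mixed"; pair_class[oo, cc] <- "mixed"

  for (s in 1:2) {
    size <- sizes[s]
    base_rate <- rate_of(size)
    for (t in seq_len(config$n_images)) {
      lam <- base_rate * exp(load %*% sig[t, ] - rowSums(load^2) / 2)
      lam <- as.vector(lam)
      R <- diag(N)
      for (clp in c("centered", "mixed", "offcentered")) {
        tgt <- config$rsc[[clp]][size]
        if (is.na(tgt) || tgt == 0) next
        idx <- which(pair_class == clp & upper.tri(pair_class), arr.ind = TRUE)
        if (nrow(idx) == 0L) next
        lam_bar <- exp(mean(log(pmax(lam[unique(c(idx))], 1e-3))))
        rho <- poisson_copula_rho(tgt, lam_bar, lam_bar)
        R[idx] <- rho; R[idx[, 2:1, drop = FALSE]] <- rho
      }
      Rc <- tryCatch(chol(R), error = function(e)
        stop("infeasible correlation targets: the implied latent ",
             "correlation matrix is not positive definite"))
      z <- matrix(stats::rnorm(config$n_trials * N), config$n_trials, N) %*% Rc
      counts[, t, s, ] <- t(matrix(
        stats::qpois(stats::pnorm(z), rep(lam, each = config$n_trials)),
        config$n_trials, N))
    }
  }

  storage.mode(counts) <- "integer"
  out <- list(counts = counts, rf = rf, stim_center = c(0, 0),
              diameters = config$stim_diam,
              baseline = data.frame(
                neuron = seq_len(N),
                mean = config$baseline_mean * base_gain,
                sd = config$baseline_sd * sqrt(base_gain)),
              platform = config$platform, config = config,
              planted_class = cls)
  class(out) <- "recording_dataset"
  out
}

#' @export
print.recording_dataset <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("recording_dataset (%s): %d neurons, %d images, 2 sizes, %d trials\n",
              x$platform, d[1], d[2], d[4]))
  invisible(x)
}
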