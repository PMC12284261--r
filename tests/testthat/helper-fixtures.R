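# Shared fixtures, built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# 4-dimensional shared-structure toy (2 filters per neuron)
toy_shared <- function() fixture("toy_shared", function() {
  set.seed(101)
  A <- matrix(rnorm(16), 4)
  Sg <- crossprod(A) / 4 + diag(4) * 0.3
  Sn <- diag(4) * 0.5; Sn[1, 3] <- Sn[3, 1] <- 0.1
  gsm_params("shared", Sg, Sn)
})

toy_independent <- function() fixture("toy_independent", function() {
  Sg <- diag(c(1.2, 0.8, 1.5, 0.6))
  Sg[1, 2] <- Sg[2, 1] <- 0.3; Sg[3, 4] <- Sg[4, 3] <- -0.2
  Sn <- diag(4) * 0.4; Sn[1, 3] <- Sn[3, 1] <- 0.15
  gsm_params("independent", Sg, Sn)
})

# small trained pair of models on surrogate ensembles (36-dim), shared
# across the model-level tests; rf 8 px in a 96 px patch
trained_fixture <- function() fixture("trained", function() {
  rf <- 8; patch <- 96
  noise <- gen_white_noise_images(300, patch, seed = 1)
  nat <- gen_surrogate_images(
    surrogate_image_config(size = patch, layout = "single", seed = 2), 300)
  gS <- build_pair_geometry(40, 0, 0)
  gI <- build_pair_geometry(0, 2.25, 0)
  pS <- suppressWarnings(train_pair_gsm(nat, noise, gS, "shared", rf_diam_px = rf))
  pI <- suppressWarnings(train_pair_gsm(nat, noise, gI, "independent", rf_diam_px = rf))
  list(rf = rf, patch = patch, geom_shared = gS, geom_indep = gI,
       shared = pS, indep = pI, snr_scalar = attr(pS, "snr_scalar"),
       noise = noise, natural = nat)
})

# surrogate stimulus pool at the training contrast scale
stim_fixture <- function(n = 40) fixture("stim", function() {
  tr <- trained_fixture()
  st <- gen_surrogate_images(
    surrogate_image_config(size = tr$patch, layout = "single", seed = 33), 40)
  0.5 + tr$snr_scalar * (st - 0.5)
})

# small planted synthetic session shared by the data-pipeline tests
session_fixture <- function() fixture("session", function() {
  cfg <- synthetic_session_config(n_centered = 12L, n_offcentered = 8L,
                                  n_images = 80L, n_trials = 20L, seed = 7L)
  ds <- gen_synthetic_session(cfg)
  lab <- classify_neurons(ds)
  list(config = cfg, dataset = ds, labels = lab,
       pair_table = build_pair_table(ds, lab))
})
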