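# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# the packaged G1 fixture with its normative model and z-scores
g1_data <- function() cached("g1_data", {
  fx <- default_fixture()
  nm <- fit_normative(fx$controls)
  zs <- compute_zscores(fx$patients, nm, features = fx$config$affected)
  list(fx = fx, nm = nm, zs = zs)
})

# three-subtype fit on the G1 z-scores (reduced optimisation effort);
# reuses the cross-validation refit when one has already been computed
g1_fit <- function() cached("g1_fit", {
  cv_model <- if (exists("cv_g1", envir = .fixture_cache))
    get("cv_g1", envir = .fixture_cache)$model
  if (!is.null(cv_model) && cv_model$k == 3) cv_model
  else sustain(g1_data()$zs, k = 3, sigma = 0.5, n_starts = 2, max_em = 12,
               seed = 77)
})

# G1 cohort with a longer follow-up schedule for endpoint analyses
g1_endpoints <- function() cached("g1_endpoints", {
  d <- g1_data()
  pat <- simulate_patients(d$fx$config, 2000, n_datasets = 3, n_visits = 5)
  list(patients = pat,
       zs = compute_zscores(pat, d$nm, features = d$fx$config$affected))
})

# small-scale cohort for fast module tests
small_data <- function() cached("small_data", {
  cfg <- small_config(seed = 4242)
  ctl <- simulate_controls(cfg, 200)
  pat <- simulate_patients(cfg, 300, n_datasets = 3, n_visits = 3)
  nm <- fit_normative(ctl)
  zs <- compute_zscores(pat, nm, features = cfg$affected)
  list(cfg = cfg, controls = ctl, patients = pat, nm = nm, zs = zs)
})
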