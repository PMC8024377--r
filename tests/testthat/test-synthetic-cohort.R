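test_that("config validation enforces the generative invariants", {
  cfg <- small_config()
  expect_s3_class(cfg, "cohort_config")
  expect_lt(abs(sum(cfg$fractions) - 1), 1e-12)
  for (s in cfg$sequences) expect_true(check_sequence(s, cfg$grid))
  bad_frac <- function() cohort_config(
    features = cfg$features, affected = cfg$affected,
    sequences = cfg$sequences, fractions = c(0.5, 0.4, 0.2),
    stage_mean = cfg$stage_mean, progression_rate = cfg$progression_rate,
    control_mean = cfg$control_mean, control_sd = cfg$control_sd,
    covariate_coefs = cfg$covariate_coefs)
  expect_error(bad_frac(), "sum to 1")
  bad_seq <- cfg$sequences
  bad_seq[[1]] <- rev(bad_seq[[1]])
  expect_error(cohort_config(
    features = cfg$features, affected = cfg$affected,
    sequences = bad_seq, fractions = cfg$fractions,
    stage_mean = cfg$stage_mean, progression_rate = cfg$progression_rate,
    control_mean = cfg$control_mean, control_sd = cfg$control_sd,
    covariate_coefs = cfg$covariate_coefs), "threshold order")
})

test_that("noiseless controls sit exactly at the configured means", {
  cfg <- small_config()
  cfg$covariate_coefs[] <- 0
  ctl <- simulate_controls(cfg, 20, noise_sd = 0)
  for (f in cfg$features)
    expect_equal(ctl[[f]], rep(cfg$control_mean[[f]], 20))
})

test_that("the generator is deterministic given its seed", {
  a <- simulate_controls(small_config(seed = 7), 50)
  b <- simulate_controls(small_config(seed = 7), 50)
  expect_identical(a, b)
  p1 <- simulate_patients(small_config(seed = 7), 40)
  p2 <- simulate_patients(small_config(seed = 7), 40)
  expect_identical(p1, p2)
  p3 <- simulate_patients(small_config(seed = 8), 40)
  expect_false(identical(p1, p3))
})

test_that("control feature means satisfy the CLT bound at n = 500", {
  cfg <- small_config(seed = 11)
  ctl <- simulate_controls(cfg, 500)
  nm <- fit_normative(ctl)
  # covariate-adjusted intercepts recover the configured means
  for (f in cfg$features) {
    resid_mean <- mean(ctl[[f]]) - mean(predict(nm, ctl)[, f])
    expect_lt(abs(resid_mean), 3 * cfg$control_sd[[f]] / sqrt(500))
  }
})

test_that("patients at stage zero with no noise match the normative law", {
  cfg <- small_config()
  cfg$stage_mean <- rep(1e-9, 3)       # baseline stage 0 for everyone
  cfg$progression_rate <- rep(0, 3)
  pat <- simulate_patients(cfg, 30, n_visits = 1, sim_noise = 0)
  expect_true(all(pat$true_stage == 0))
  mu <- sustainMS:::normative_mean(cfg, pat)
  offs <- rep_len(cfg$dataset_offsets, 3)[
    as.integer(sub("trial", "", pat$dataset_id))]
  for (j in seq_along(cfg$features)) {
    expected <- mu[, j] + offs * cfg$control_sd[[j]]
    expect_equal(pat[[cfg$features[j]]], expected, tolerance = 1e-12)
  }
})

test_that("a degenerate mixture assigns every subject to subtype 1", {
  cfg <- small_config()
  cfg$fractions <- c(1, 0, 0)
  pat <- simulate_patients(cfg, 50)
  expect_true(all(pat$true_subtype == 1))
})

test_that("planted subtype proportions match the mixture at n = 2000", {
  d <- g1_data()
  base <- baseline_visits(d$fx$patients)
  frac <- table(base$true_subtype) / nrow(base)
  # exact binomial 99% bounds for each planted fraction
  for (c in 1:3) {
    ci <- stats::binom.test(sum(base$true_subtype == c), nrow(base),
                            conf.level = 0.99)$conf.int
    expect_gte(d$fx$config$fractions[c], ci[1])
    expect_lte(d$fx$config$fractions[c], ci[2])
  }
})

test_that("pathology is monotone in stage when noise is removed", {
  cfg <- small_config()
  grid <- cfg$grid
  for (s in cfg$sequences) {
    G <- event_trajectory(grid, s)
    expect_true(all(diff(t(G)) >= -1e-12))
  }
  # raw volumes are non-increasing in stage under the flip convention
  cfg$progression_rate <- rep(8, 3)    # fast progression over visits
  pat <- simulate_patients(cfg, 60, n_visits = 4, sim_noise = 0)
  pat$pred <- sustainMS:::normative_mean(cfg, pat)[, 1]
  by_subj <- split(pat, pat$subject_id)
  for (p in by_subj) {
    p <- p[order(p$visit_time), ]
    shift <- p$f1 - p$pred               # f1 is a flipped (volume-like) feature
    expect_true(all(diff(p$true_stage) >= 0))
    expect_true(all(diff(shift) <= 1e-8))
  }
})

test_that("cohort CSV round-trips exactly", {
  d <- small_data()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d$patients, tmp)
  back <- read_cohort(tmp)
  expect_identical(names(back), names(d$patients))
  for (col in names(d$patients)) {
    a <- back[[col]]
    b <- d$patients[[col]]
    if (is.numeric(b)) {                     # exact value round-trip
      expect_identical(as.numeric(a), unname(as.numeric(b)), label = col)
    } else {
      expect_identical(unname(a), unname(b), label = col)
    }
  }
})

test_that("mean EDSS increases across true-stage tertiles in G1", {
  d <- g1_data()
  base <- baseline_visits(d$fx$patients)
  tert <- stage_tertiles(base$true_stage)
  m <- tapply(base$edss, tert$group, mean)
  expect_lt(m[["low"]], m[["mid"]])
  expect_lt(m[["mid"]], m[["high"]])
})

test_that("fixture structure matches its documented design", {
  d <- g1_data()
  expect_equal(d$fx$config$fractions, c(0.43, 0.32, 0.25))
  expect_equal(d$fx$config$grid$E, 39)
  expect_equal(length(d$fx$config$affected), 13)
  expect_equal(length(unique(d$fx$patients$subject_id)), 2000)
  expect_equal(length(unique(d$fx$patients$dataset_id)), 3)
  # regenerating with the stored seed reproduces the tables exactly
  again <- default_fixture()
  expect_identical(again$patients, d$fx$patients)
  expect_identical(again$controls, d$fx$controls)
})
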