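test_that("noiseless controls give exact coefficient recovery", {
  cfg <- small_config(seed = 3)
  ctl <- simulate_controls(cfg, 100, noise_sd = 0)
  nm <- suppressWarnings(fit_normative(ctl))
  # an exactly-zero residual SD makes z-scores undefined
  nm0 <- nm
  nm0$residual_sd[1] <- 0
  expect_error(compute_zscores(ctl, nm0), "zero control residual SD")
  for (j in seq_along(cfg$features)) {
    est <- nm$coefficients[, j]
    truth <- c(cfg$control_mean[[j]], cfg$covariate_coefs[j, ])
    expect_lt(max(abs(est - truth)), 1e-8)
  }
})

test_that("coefficients are recovered within 4 SEs under noise", {
  cfg <- small_config(seed = 5)
  ctl <- simulate_controls(cfg, 500)
  nm <- fit_normative(ctl)
  X <- sustainMS:::normative_design(ctl)
  XtXinv <- solve(crossprod(X))
  for (j in seq_along(cfg$features)) {
    se <- sqrt(diag(XtXinv)) * nm$residual_sd[j]
    truth <- c(cfg$control_mean[[j]], cfg$covariate_coefs[j, ])
    expect_true(all(abs(nm$coefficients[, j] - truth) < 4 * se))
    # residual SD estimates the configured noise scale
    expect_lt(abs(nm$residual_sd[[j]] / cfg$control_sd[[j]] - 1), 0.2)
  }
})

test_that("degenerate covariate designs are rejected", {
  cfg <- small_config()
  ctl <- simulate_controls(cfg, 50)
  ctl$age <- 40                        # constant age -> age2 collinear
  expect_error(fit_normative(ctl), "rank")
  expect_error(fit_normative(simulate_controls(cfg, 50)[1:5, ]),
               "at least 10")
})

test_that("z-scores follow the definition and the sign-flip rule", {
  d <- small_data()
  nm <- d$nm
  one <- d$controls[1, ]
  pred <- predict(nm, one)
  # value exactly at the normative prediction (mean control residual is 0
  # up to numerical error for OLS) -> z = 0
  for (f in nm$features) one[[f]] <- pred[, f]
  z0 <- compute_zscores(as_cohort_table(one), nm)
  expect_lt(max(abs(as.numeric(z0[1, nm$features]))), 1e-10)
  # a flipped feature 2 control-SDs below prediction scores z = +2
  two <- one
  two$f1 <- pred[, "f1"] - 2 * nm$residual_sd[["f1"]]
  z2 <- compute_zscores(as_cohort_table(two), nm)
  expect_equal(z2$f1[1], 2, tolerance = 1e-10)
  # an unflipped (lesion-like) feature 1 SD above prediction scores z = +1
  les <- one
  les$f8 <- pred[, "f8"] + 1 * nm$residual_sd[["f8"]]
  z1 <- compute_zscores(as_cohort_table(les), nm, flip = character(0))
  expect_equal(z1$f8[1], 1, tolerance = 1e-10)
})

test_that("held-out control z-scores are standard-normal-like", {
  cfg <- small_config(seed = 21)
  ctl <- simulate_controls(cfg, 1000)
  nm <- fit_normative(ctl[1:500, ])
  z <- compute_zscores(as_cohort_table(ctl[501:1000, ]), nm)
  for (f in nm$features) {
    expect_lt(abs(mean(z[[f]])), 0.1)
    expect_lt(abs(stats::sd(z[[f]]) - 1), 0.1)
  }
})

test_that("z-scores are invariant to a common rescaling of a feature", {
  d <- small_data()
  z1 <- compute_zscores(d$patients, d$nm, features = "f2")
  scaled_ctl <- d$controls
  scaled_pat <- d$patients
  scaled_ctl$f2 <- scaled_ctl$f2 * 10
  scaled_pat$f2 <- scaled_pat$f2 * 10
  nm10 <- fit_normative(scaled_ctl)
  z10 <- compute_zscores(scaled_pat, nm10, features = "f2")
  expect_equal(z10$f2, z1$f2, tolerance = 1e-8)
})

test_that("cohen_d matches the pooled-SD formula and simulation", {
  expect_equal(cohen_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohen_d(c(-1, 1), c(0, 2)), 1 / sqrt(2), tolerance = 1e-12)
  expect_error(cohen_d(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(cohen_d(1, c(1, 2)), ">= 2")
  set.seed(9)
  a <- stats::rnorm(1e4)
  b <- stats::rnorm(1e4, 1)
  expect_lt(abs(cohen_d(a, b) - 1), 0.05)
})

test_that("feature selection is monotone in the threshold and errors when empty", {
  d <- small_data()
  s_low <- select_features(d$controls, d$patients, model = d$nm,
                           threshold = 0.3)
  s_mid <- select_features(d$controls, d$patients, model = d$nm,
                           threshold = 0.8)
  expect_true(all(attr(s_mid, "retained") %in% attr(s_low, "retained")))
  expect_error(select_features(d$controls, d$patients, model = d$nm,
                               threshold = Inf), "no features pass")
  # patients indistinguishable from controls: all D ~ 0
  fake <- d$controls
  fake$arm <- "placebo"
  fake$edss <- NULL
  fake <- as_cohort_table(cbind(fake, edss = NA_real_))
  expect_error(select_features(d$controls, fake, model = d$nm),
               "no features pass")
})

test_that("region arbitration keeps volumes for GM and ratios for WM", {
  d <- g1_data()
  # force the cerebellar WM volume to pass as well: both it and the
  # cerebellar T1/T2 ratio now exceed the threshold, so the volume must be
  # dropped in favour of the white-matter ratio
  pat <- d$fx$patients
  pat$wmv_cerebellum <- pat$wmv_cerebellum -
    2 * d$nm$residual_sd[["wmv_cerebellum"]]
  sel <- select_features(d$fx$controls, pat, model = d$nm, threshold = 0.5)
  expect_gt(abs(sel$cohen_d[sel$feature == "wmv_cerebellum"]), 0.5)
  kept <- attr(sel, "retained")
  expect_false("wmv_cerebellum" %in% kept)
  expect_true("t1t2_cerebellum" %in% kept)
  expect_true("gmv_frontal" %in% kept)         # GM volumes stay
})
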