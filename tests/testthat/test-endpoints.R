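test_that("the EDSS progression threshold follows the baseline bands", {
  expect_equal(edss_increase_threshold(0), 1.5)
  expect_equal(edss_increase_threshold(0.5), 1)
  expect_equal(edss_increase_threshold(3), 1)
  expect_equal(edss_increase_threshold(5.5), 1)
  expect_equal(edss_increase_threshold(6), 0.5)
  expect_equal(edss_increase_threshold(10), 0.5)
  expect_error(edss_increase_threshold(2.3), "lattice")
  expect_error(edss_increase_threshold(-1), "lattice")
})

test_that("confirmed progression detection follows the sustained-worsening rule", {
  # sustained for >= 168 days: event at onset
  r <- detect_cdp(c(0, 90, 270), c(2, 3, 3))
  expect_true(r$event)
  expect_equal(r$time, 90)
  # worsening that reverts before confirmation: censored at last visit
  r <- detect_cdp(c(0, 90, 270), c(2, 3, 2))
  expect_false(r$event)
  expect_equal(r$time, 270)
  # no confirmatory visit: unconfirmable
  r <- detect_cdp(c(0, 90), c(2, 3))
  expect_false(r$event)
  expect_equal(r$time, 90)
  # interim visit dips below threshold: rejected under the strict rule,
  # accepted when only the confirming visit is required
  times <- c(0, 90, 180, 300)
  edss <- c(2, 3, 2.5, 3)
  expect_false(detect_cdp(times, edss)$event)
  expect_true(detect_cdp(times, edss, require_interim = FALSE)$event)
  expect_error(detect_cdp(c(0, 90, 90), c(2, 3, 3)), "strictly increasing")
})

test_that("appending worsening visits never removes or delays an event", {
  set.seed(81)
  for (rep in 1:25) {
    n <- sample(3:7, 1)
    times <- sort(sample(0:900, n))
    times <- times + seq_along(times)   # ensure strictly increasing
    edss <- round(pmin(10, pmax(0, cumsum(
      c(stats::runif(1, 0, 6), stats::rnorm(n - 1, 0.3, 0.7))))) * 2) / 2
    base <- detect_cdp(times, edss)
    ext <- detect_cdp(c(times, max(times) + 200, max(times) + 400),
                      c(edss, 10, 10))
    if (base$event) {
      expect_true(ext$event)
      expect_lte(ext$time, base$time)
    }
  }
})

test_that("the log-rank statistic matches the hand-computed table", {
  rec <- data.frame(time = c(1, 2, 3, 10, 20, 30), event = TRUE,
                    group = rep(c("a", "b"), each = 3))
  lr <- logrank_compare(rec)
  # O_a = 3, E_a = 0.5 + 0.4 + 0.25, V = 0.25 + 0.24 + 0.1875
  expect_equal(lr$chisq, (3 - 1.15)^2 / 0.6775, tolerance = 1e-6)
  expect_equal(lr$df, 1)
  expect_equal(lr$p, stats::pchisq((3 - 1.15)^2 / 0.6775, 1,
                                   lower.tail = FALSE), tolerance = 1e-9)
  # identical groups: no signal
  dup <- data.frame(time = rep(c(1, 2, 5), 2), event = TRUE,
                    group = rep(c("a", "b"), each = 3))
  lr0 <- logrank_compare(dup)
  expect_lt(lr0$chisq, 1e-8)
  expect_gt(lr0$p, 0.99)
  expect_error(logrank_compare(data.frame(time = 1:4, event = FALSE,
                                          group = c("a", "a", "b", "b"))),
               "no events")
})

test_that("label-permuted log-rank p-values are uniform", {
  set.seed(82)
  rec <- data.frame(time = stats::rexp(40), event = TRUE,
                    group = rep(c("a", "b"), 20))
  ps <- replicate(200, {
    shuffled <- rec
    shuffled$group <- sample(rec$group)
    logrank_compare(shuffled)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("hazard contrasts recover null and report sane intervals", {
  set.seed(83)
  rec <- data.frame(time = stats::rexp(300), event = TRUE,
                    group = rep(c("ref", "other"), each = 150))
  hr <- suppressWarnings(hazard_contrast(rec, reference = "ref"))
  expect_gt(hr$upper, 1)
  expect_lt(hr$lower, 1)
  expect_true(hr$lower < hr$hr & hr$hr < hr$upper)
})

test_that("stage tertiles use empirical cuts with ties to the lower group", {
  t1 <- stage_tertiles(1:39)
  expect_equal(unname(t1$cuts), c(13, 26))
  expect_equal(as.integer(table(t1$group)), c(13L, 13L, 13L))
  expect_equal(t1$group[13], factor("low", levels = c("low", "mid", "high")))
  expect_error(stage_tertiles(rep(5, 30)), "distinct")
  set.seed(84)
  x <- sample(1:39, 200, replace = TRUE)
  g <- stage_tertiles(x)
  expect_true(max(table(g$group)) - min(table(g$group)) <= 2 * sum(duplicated(x)) + 1)
})

test_that("annualised relapse rates follow the person-years definition", {
  one <- data.frame(subject_id = "s1", dataset_id = "d", arm = "placebo",
                    visit_time = c(0, 1, 2), age = 40, sex = 1, tiv = 1500,
                    edss = 2, relapses_since_last_visit = c(NA, 1, 1),
                    gad_count = 0)
  arr <- annualized_relapse_rate(as_cohort_table(one),
                                 data.frame(subject_id = "s1", group = "g"))
  expect_equal(arr$rate, 1)
  expect_equal(arr$person_years, 2)
  # zero relapses: rate 0 with finite SE from the regression contract
  zero <- one
  zero$relapses_since_last_visit <- c(NA, 0L, 0L)
  arr0 <- annualized_relapse_rate(as_cohort_table(zero),
                                  data.frame(subject_id = "s1", group = "g"))
  expect_equal(arr0$rate, 0)
  expect_true(is.finite(arr0$se))
})

test_that("relapse rates are invariant to splitting follow-up intervals", {
  d <- g1_endpoints()
  pat <- d$patients[d$patients$arm == "placebo", ]
  groups <- data.frame(subject_id = unique(pat$subject_id), group = "all")
  full <- annualized_relapse_rate(pat, groups)
  # merging each subject's two middle intervals leaves totals unchanged
  merged <- pat[pat$visit_time != 1, ]
  idx2 <- merged$visit_time == 2
  add <- pat$relapses_since_last_visit[pat$visit_time == 1]
  names(add) <- pat$subject_id[pat$visit_time == 1]
  merged$relapses_since_last_visit[idx2] <-
    merged$relapses_since_last_visit[idx2] +
    add[merged$subject_id[idx2]]
  half <- annualized_relapse_rate(merged, groups)
  expect_equal(half$rate, full$rate, tolerance = 1e-12)
  expect_equal(half$relapses, full$relapses)
})

test_that("the concordance index enumerates comparable pairs correctly", {
  expect_equal(concordance_index(c(3, 2, 1), c(1, 2, 3), c(TRUE, TRUE, TRUE)), 1)
  expect_equal(concordance_index(c(1, 2, 3), c(1, 2, 3), c(TRUE, TRUE, TRUE)), 0)
  expect_equal(concordance_index(c(3, 1, 2), c(1, 2, 3), rep(TRUE, 3)), 2 / 3)
  # censoring: pairs whose smaller time is censored are unusable
  expect_error(concordance_index(c(2, 1), c(1, 5), c(FALSE, TRUE)),
               "no comparable")
  expect_error(concordance_index(1, 1, TRUE), "no comparable")
  # complementarity without ties
  set.seed(85)
  risk <- stats::rnorm(30)
  tm <- stats::rexp(30)
  ev <- stats::runif(30) < 0.7
  if (sum(ev) > 2) {
    ci_a <- concordance_index(risk, tm, ev)
    ci_b <- concordance_index(-risk, tm, ev)
    expect_equal(ci_a + ci_b, 1, tolerance = 1e-12)
  }
  # agreement with the survival package on random censored data
  ref <- survival::concordance(survival::Surv(tm, ev) ~ risk, reverse = TRUE)
  expect_equal(concordance_index(risk, tm, ev), unname(ref$concordance),
               tolerance = 1e-10)
})

test_that("treatment response reproduces planted slope arithmetic", {
  # noise-free: placebo slope 0.10/yr, treated 0.05/yr -> -50%
  n <- 40
  long <- expand.grid(subject_id = sprintf("s%02d", 1:n), visit_time = 0:3)
  long$dataset_id <- rep(rep(c("t1", "t2"), n / 2), 4)
  long$arm <- rep(rep(c("placebo", "treated"), each = n / 2), 4)
  slope <- ifelse(long$arm == "placebo", 0.10, 0.05)
  long$edss <- 2 + slope * long$visit_time
  long$age <- 40; long$sex <- 0; long$tiv <- 1500
  tr <- treatment_response(long,
                           data.frame(subject_id = sprintf("s%02d", 1:n),
                                      subtype = 1))
  expect_equal(tr$response_pct, -50, tolerance = 1e-6)
  expect_equal(tr$slope_placebo, 0.10, tolerance = 1e-8)
  expect_true(tr$defined)
})

test_that("annual stage change fits exact per-subject slopes", {
  asg <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                    visit_time = rep(0:2, 2),
                    stage_mode = c(10, 11, 12, 7, 7, 7))
  groups <- data.frame(subject_id = c("a", "b"), group = c("g1", "g2"))
  out <- annual_stage_change(asg, groups)
  expect_equal(out$slope[out$group == "g1"], 1)
  expect_equal(out$slope[out$group == "g2"], 0)
  expect_error(annual_stage_change(asg[c(1, 4), ], groups), ">= 2")
})

test_that("subtype stability counts constant-assignment subjects", {
  asg <- data.frame(subject_id = rep(c("a", "b", "c"), each = 2),
                    subtype = c(1, 1, 2, 3, 2, 2))
  expect_equal(subtype_stability(asg), 2 / 3)
  stable <- data.frame(subject_id = rep("a", 3), subtype = 2)
  expect_equal(subtype_stability(stable), 1)
  flip <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                     subtype = c(1, 2, 2, 3))
  expect_equal(subtype_stability(flip), 0)
})
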