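# Clinical endpoints: confirmed disability progression, survival
# comparisons, relapse rates, concordance, treatment response, stage
# dynamics and assignment stability.

DAYS_PER_YEAR <- 365.25

#' Required EDSS increase for confirmed progression
#'
#' The progression threshold depends on the baseline score: a 1.5-point
#' increase from a baseline of 0, a 1-point increase from 0.5-5.5, and a
#' 0.5-point increase above 5.5.
#'
#' @param baseline_edss baseline EDSS value(s) on the 0-10 half-point
#'   lattice.
#' @return Required increase(s): 1.5, 1.0 or 0.5.
#' @export
edss_increase_threshold <- function(baseline_edss) {
  if (any(is.na(baseline_edss)) ||
      any(baseline_edss < 0 | baseline_edss > 10 |
            baseline_edss * 2 != round(baseline_edss * 2)))
    stop("baseline EDSS must lie on the 0-10 half-point lattice")
  ifelse(baseline_edss == 0, 1.5, ifelse(baseline_edss <= 5.5, 1, 0.5))
}

#' Detect 24-week confirmed disability progression
#'
#' Scans a subject's EDSS series in visit order. A candidate onset at
#' visit t qualifies when the increase over baseline meets the
#' baseline-dependent threshold and every subsequent visit up to and
#' including the first visit at least `confirm_days` later also meets it
#' (the strictest reading of "sustained"; set `require_interim = FALSE`
#' to demand only the confirming visit). An onset with no visit
#' `confirm_days` later is unconfirmable. Returns the earliest qualifying
#' onset, else censoring at the last visit.
#'
#' @param times visit times in days, strictly increasing, first = baseline.
#' @param edss EDSS at each visit.
#' @param confirm_days confirmation window (default 168 = 24 weeks).
#' @param require_interim require all interim visits to meet the
#'   threshold (default TRUE).
#' @return List with `event` (logical) and `time` (onset time if event,
#'   last visit time otherwise, in days).
#' @export
detect_cdp <- function(times, edss, confirm_days = 168,
                       require_interim = TRUE) {
  if (length(times) != length(edss)) stop("times and edss lengths differ")
  if (length(times) < 2)
    return(list(event = FALSE, time = times[length(times)]))
  if (any(diff(times) <= 0)) stop("visit times must be strictly increasing")
  thr <- edss_increase_threshold(edss[1])
  meets <- edss - edss[1] >= thr
  for (t in 2:length(times)) {
    if (!meets[t]) next
    conf <- which(times >= times[t] + confirm_days)
    if (!length(conf)) next              # unconfirmable
    conf <- conf[1]
    span <- if (require_interim) seq(t, conf) else c(t, conf)
    if (all(meets[span])) return(list(event = TRUE, time = times[t]))
  }
  list(event = FALSE, time = times[length(times)])
}

#' Build per-subject CDP survival records from a cohort
#'
#' Applies [detect_cdp()] to each subject's EDSS series (visit times are
#' converted from years to days) and returns one survival record per
#' subject with the baseline covariates and any grouping columns.
#'
#' @param cohort a `cohort_table` with `edss`.
#' @param groups optional data.frame of per-subject labels to join by
#'   `subject_id` (e.g. assigned subtype or stage tertile).
#' @param confirm_days confirmation window in days.
#' @return data.frame with `subject_id`, `time` (years, > 0), `event`,
#'   `baseline_edss`, `age`, `sex`, `dataset_id`, `arm` plus joined
#'   columns.
#' @export
cdp_survival <- function(cohort, groups = NULL, confirm_days = 168) {
  sp <- split(seq_len(nrow(cohort)), cohort$subject_id)
  rows <- lapply(names(sp), function(sid) {
    i <- sp[[sid]][order(cohort$visit_time[sp[[sid]]])]
    ok <- !is.na(cohort$edss[i])
    i <- i[ok]
    if (length(i) < 2) return(NULL)
    d <- detect_cdp(cohort$visit_time[i] * DAYS_PER_YEAR,
                    cohort$edss[i], confirm_days)
    data.frame(subject_id = sid,
               time = max(d$time / DAYS_PER_YEAR, 1e-6),
               event = d$event,
               baseline_edss = cohort$edss[i[1]],
               age = cohort$age[i[1]], sex = cohort$sex[i[1]],
               dataset_id = cohort$dataset_id[i[1]],
               arm = cohort$arm[i[1]])
  })
  out <- do.call(rbind, rows)
  if (!is.null(groups)) out <- merge(out, groups, by = "subject_id")
  rownames(out) <- NULL
  out
}

#' k-group log-rank test on CDP survival records
#'
#' @param records data.frame with `time`, `event` and a `group` column.
#' @param group name of the grouping column (default `"group"`).
#' @return List with `chisq`, `df` and the two-sided `p` value.
#' @export
logrank_compare <- function(records, group = "group") {
  g <- factor(records[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (sum(records$event) < 1) stop("no events: log-rank undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = cbind(records, g = g))
  df <- nlevels(g) - 1
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Proportional-hazards contrast between groups
#'
#' Cox regression of CDP time on group (first level of `reference` is the
#' baseline) with optional covariate adjustment; returns hazard ratios
#' with 95% Wald confidence intervals.
#'
#' @param records survival records as from [cdp_survival()].
#' @param group grouping column name.
#' @param reference reference group level.
#' @param covariates optional covariate column names to adjust for.
#' @return data.frame with one row per non-reference level: `hr`, `lower`,
#'   `upper`, `p`.
#' @export
hazard_contrast <- function(records, group = "group", reference = NULL,
                            covariates = NULL) {
  g <- factor(records[[group]])
  if (!is.null(reference)) g <- stats::relevel(g, ref = as.character(reference))
  n_events <- sum(records$event)
  n_par <- (nlevels(g) - 1) + length(covariates)
  if (n_events < 10 * n_par)
    warning("fewer than 10 events per fitted parameter (", n_events,
            " events, ", n_par, " parameters)")
  dat <- cbind(records, .g = g)
  rhs <- paste(c(".g", covariates), collapse = " + ")
  fit <- survival::coxph(stats::as.formula(
    paste("survival::Surv(time, event) ~", rhs)), data = dat)
  if (any(is.na(fit$coefficients)))
    stop("Cox model failed (separation or collinear covariates)")
  sm <- summary(fit)
  keep <- grep("^\\.g", rownames(sm$coefficients))
  data.frame(
    contrast = sub("^\\.g", "", rownames(sm$coefficients)[keep]),
    hr = sm$coefficients[keep, "exp(coef)"],
    lower = sm$conf.int[keep, "lower .95"],
    upper = sm$conf.int[keep, "upper .95"],
    p = sm$coefficients[keep, "Pr(>|z|)"],
    row.names = NULL
  )
}

#' Split baseline stages into tertiles
#'
#' Empirical tertile cuts (type-1 quantiles); observations equal to a cut
#' go to the lower group.
#'
#' @param stages numeric baseline stages.
#' @return List with `group` (factor `low`/`mid`/`high`) and `cuts`.
#' @export
stage_tertiles <- function(stages) {
  stages <- stages[!is.na(stages)]
  if (length(unique(stages)) < 3)
    stop("need at least 3 distinct stage values for tertiles")
  cuts <- stats::quantile(stages, c(1, 2) / 3, type = 1, names = FALSE)
  group <- factor(ifelse(stages <= cuts[1], "low",
                         ifelse(stages <= cuts[2], "mid", "high")),
                  levels = c("low", "mid", "high"))
  list(group = group, cuts = cuts)
}

#' Annualised relapse rate per group
#'
#' Point estimate sum(relapses) / sum(person-years) per group; standard
#' errors from a Poisson regression with log person-years offset.
#' Relapse counts are `relapses_since_last_visit` summed per subject over
#' follow-up.
#'
#' @param cohort a patient `cohort_table`.
#' @param groups data.frame with `subject_id` and `group`.
#' @return data.frame per group: `relapses`, `person_years`, `rate`, `se`.
#' @export
annualized_relapse_rate <- function(cohort, groups) {
  sp <- split(seq_len(nrow(cohort)), cohort$subject_id)
  per <- lapply(names(sp), function(sid) {
    i <- sp[[sid]][order(cohort$visit_time[sp[[sid]]])]
    fu <- max(cohort$visit_time[i]) - min(cohort$visit_time[i])
    data.frame(subject_id = sid,
               relapses = sum(cohort$relapses_since_last_visit[i],
                              na.rm = TRUE),
               person_years = fu)
  })
  per <- do.call(rbind, per)
  per <- merge(per, groups, by = "subject_id")
  per <- per[per$person_years > 0, ]
  if (sum(per$person_years) <= 0) stop("zero person-years of follow-up")
  g <- factor(per$group)
  fit <- if (nlevels(g) > 1) {
    suppressWarnings(stats::glm(relapses ~ 0 + g + offset(log(person_years)),
                                family = stats::poisson(), data = per))
  } else {
    suppressWarnings(stats::glm(relapses ~ 1 + offset(log(person_years)),
                                family = stats::poisson(), data = per))
  }
  co <- summary(fit)$coefficients
  rownames(co) <- if (nlevels(g) > 1) sub("^g", "", rownames(co)) else levels(g)
  agg <- data.frame(
    group = levels(g),
    relapses = tapply(per$relapses, g, sum),
    person_years = tapply(per$person_years, g, sum)
  )
  agg$rate <- agg$relapses / agg$person_years
  agg$se <- agg$rate * co[agg$group, "Std. Error"]
  rownames(agg) <- NULL
  agg
}

#' Concordance index for (possibly censored) survival
#'
#' Over all comparable pairs -- pairs where the smaller observed time is
#' an event -- the fraction in which the higher risk score has the
#' shorter survival; risk ties count 1/2. 1 is perfect prediction, 0.5
#' chance, 0 perfect anti-prediction.
#'
#' @param risk numeric risk scores (higher = predicted earlier event).
#' @param times observed times.
#' @param events event indicators (TRUE = event, FALSE = censored).
#' @return The concordance index in `[0, 1]`.
#' @export
concordance_index <- function(risk, times, events) {
  n <- length(risk)
  if (length(times) != n || length(events) != n)
    stop("inputs must have equal length")
  events <- as.logical(events)
  num <- 0
  den <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ti <- times[i]; tj <- times[j]
      if (ti == tj) next
      first <- if (ti < tj) i else j
      if (!events[first]) next           # smaller time censored: unusable
      den <- den + 1
      d_risk <- risk[first] - risk[c(i, j)[c(i, j) != first]]
      num <- num + (if (d_risk > 0) 1 else if (d_risk == 0) 0.5 else 0)
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

#' Treatment response as percentage change in EDSS worsening
#'
#' Per subtype, fits a linear mixed-effects model of EDSS on arm, time
#' and their interaction with random intercepts for subject nested in
#' dataset, and reports the treated-versus-placebo difference in EDSS
#' slope as a percentage of the placebo slope with a delta-method SE.
#' A placebo slope indistinguishable from zero flags the response as
#' undefined.
#'
#' @param cohort patient `cohort_table` with `edss`, `arm`, `visit_time`.
#' @param subtypes data.frame with `subject_id` and `subtype`.
#' @return data.frame per subtype: `slope_placebo`, `slope_treated`,
#'   `response_pct`, `se_pct`, `p_interaction`, `defined`.
#' @export
treatment_response <- function(cohort, subtypes) {
  dat <- merge(cohort, subtypes, by = "subject_id")
  dat <- dat[!is.na(dat$edss) & dat$arm %in% c("placebo", "treated"), ]
  out <- lapply(sort(unique(dat$subtype)), function(st) {
    d <- dat[dat$subtype == st, ]
    d$treated <- as.integer(d$arm == "treated")
    if (length(unique(d$treated)) < 2)
      stop("both arms required within subtype ", st)
    fit <- tryCatch(
      suppressWarnings(suppressMessages(lme4::lmer(
        edss ~ treated * visit_time + (1 | dataset_id / subject_id),
        data = d, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    calc.derivs = FALSE)))),
      error = function(e) stats::lm(edss ~ treated * visit_time, data = d))
    b <- if (inherits(fit, "lm")) stats::coef(fit) else lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    s_p <- b[["visit_time"]]
    s_i <- b[["treated:visit_time"]]
    i_p <- which(names(b) == "visit_time")
    i_i <- which(names(b) == "treated:visit_time")
    defined <- abs(s_p) > 2 * sqrt(V[i_p, i_p])
    resp <- 100 * s_i / s_p
    # delta method for g = 100 * s_i / s_p
    grad <- c(-100 * s_i / s_p^2, 100 / s_p)
    Vsub <- V[c(i_p, i_i), c(i_p, i_i)]
    se <- sqrt(drop(t(grad) %*% Vsub %*% grad))
    z <- s_i / sqrt(V[i_i, i_i])
    data.frame(subtype = st, slope_placebo = s_p,
               slope_treated = s_p + s_i, response_pct = resp,
               se_pct = se, p_interaction = 2 * stats::pnorm(-abs(z)),
               defined = defined)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Annual change in assigned stage per group
#'
#' Per-subject least-squares slope of stage against years over subjects
#' with at least two staged visits, averaged per group with the standard
#' error of the mean.
#'
#' @param assignments data.frame with `subject_id`, `visit_time` and a
#'   stage column.
#' @param groups data.frame with `subject_id` and `group`.
#' @param stage_col which stage column to use (default `"stage_mode"`).
#' @return data.frame per group: `n`, `slope`, `se`.
#' @export
annual_stage_change <- function(assignments, groups,
                                stage_col = "stage_mode") {
  sp <- split(seq_len(nrow(assignments)), assignments$subject_id)
  slopes <- vapply(sp, function(i) {
    t <- assignments$visit_time[i]
    s <- assignments[[stage_col]][i]
    if (length(unique(t)) < 2) return(NA_real_)
    sum((t - mean(t)) * (s - mean(s))) / sum((t - mean(t))^2)
  }, numeric(1))
  per <- data.frame(subject_id = names(sp), slope = slopes)
  per <- merge(per[!is.na(per$slope), ], groups, by = "subject_id")
  if (!nrow(per)) stop("no subjects with >= 2 staged visits")
  g <- factor(per$group)
  data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    slope = tapply(per$slope, g, mean),
    se = tapply(per$slope, g, function(x) stats::sd(x) / sqrt(length(x))),
    row.names = NULL
  )
}

#' Stability of subtype assignment over visits
#'
#' Fraction of subjects with at least two visits whose modal subtype is
#' identical at every visit.
#'
#' @param assignments data.frame with `subject_id` and `subtype`.
#' @return Scalar fraction in `[0, 1]`.
#' @export
subtype_stability <- function(assignments) {
  sp <- split(assignments$subtype, assignments$subject_id)
  multi <- sp[lengths(sp) >= 2]
  if (!length(multi)) return(NA_real_)
  mean(vapply(multi, function(s) length(unique(s)) == 1, logical(1)))
}
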