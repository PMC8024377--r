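# Synthetic multi-trial cohort simulator.
#
# Stands in for the inaccessible clinical-trial datasets: a healthy-control
# stratum whose features depend on head size, sex and age, and a patient
# stratum drawn from latent subtypes, each with its own event sequence and
# stage distribution, observed longitudinally across several pseudo-trials.

# each table type draws from its own RNG stream derived from the master
# seed by a fixed offset, so tables can be regenerated independently
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  expr
}

round_half <- function(x) round(x * 2) / 2

draw_covariates <- function(n, patient) {
  if (patient) {
    age <- pmin(70, pmax(18, stats::rnorm(n, 43, 10)))
    sex <- stats::rbinom(n, 1, 0.64)
  } else {
    age <- pmin(75, pmax(20, stats::rnorm(n, 45, 13)))
    sex <- stats::rbinom(n, 1, 0.5)
  }
  tiv <- stats::rnorm(n, 1450, 120)
  data.frame(age = age, sex = sex, tiv = tiv)
}

# normative mean of each feature given covariates (n x F matrix)
normative_mean <- function(config, cov) {
  X <- cbind(cov$tiv, cov$sex, cov$age, cov$age^2)
  sweep(X %*% t(config$covariate_coefs), 2, config$control_mean, `+`)
}

# stage distribution: geometric with given mean, truncated to 0..E
stage_probs <- function(mean_stage, E) {
  p <- 1 / (1 + mean_stage)
  pr <- p * (1 - p)^(0:E)
  pr / sum(pr)
}

#' Simulate a healthy-control cohort
#'
#' One visit per subject; each feature is its control mean plus covariate
#' effects (total intracranial volume, sex, age, age squared) plus
#' Gaussian residual noise. Controls carry no EDSS or relapse data.
#'
#' @param config a [cohort_config()].
#' @param n number of control subjects (>= 1).
#' @param noise_sd optional per-feature residual SD override (raw scale);
#'   defaults to `config$control_sd`. Use 0 for noiseless checks.
#' @return A `cohort_table` data.frame, one row per visit.
#' @export
simulate_controls <- function(config, n, noise_sd = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(n) != 1 || n < 1) stop("n must be a positive count")
  if (is.null(noise_sd)) noise_sd <- config$control_sd
  noise_sd <- rep_len(noise_sd, length(config$features))
  local_seed(config$seed + 1L, {
    cov <- draw_covariates(n, patient = FALSE)
    mu <- normative_mean(config, cov)
    eps <- matrix(stats::rnorm(n * ncol(mu)), n) %*% diag(noise_sd, ncol(mu))
    feat <- mu + eps
    colnames(feat) <- config$features
    out <- data.frame(
      subject_id = sprintf("HC%04d", seq_len(n)),
      dataset_id = "controls", arm = "control", visit_time = 0,
      cov, feat, edss = NA_real_, relapses_since_last_visit = NA_integer_,
      gad_count = NA_integer_, check.names = FALSE
    )
    as_cohort_table(out)
  })
}

#' Simulate a longitudinal patient cohort
#'
#' Each subject draws a latent subtype from the mixture fractions and a
#' baseline stage from that subtype's truncated-geometric stage law; the
#' stage advances by the subtype's progression rate (rounded to integer
#' stages, capped at E) over follow-up. Affected features sit at the
#' expected trajectory value for the subject's stage -- shifted downwards
#' on the raw scale for volumes and T1/T2 ratios and upwards for lesion
#' volume -- with residual noise of `config$sim_noise` control-SDs.
#' Unaffected features follow the control law. EDSS, relapses and
#' contrast-enhancing lesion counts are coupled to subtype and stage;
#' disability progression is realised as a latent exponential event time
#' whose hazard is subtype-specific, adding a sustained EDSS step. The
#' treated arm multiplies EDSS slope, relapse rate and progression hazard
#' by the subtype's treatment multiplier.
#'
#' @param config a [cohort_config()].
#' @param n number of patients (>= number of subtypes).
#' @param n_datasets number of pseudo-trials; subjects are assigned
#'   round-robin and each dataset adds its configured offset.
#' @param n_visits visits per subject.
#' @param visit_spacing years between visits (default 1).
#' @param sim_noise optional override of the z-scale residual SD.
#' @return A `cohort_table` data.frame with ground-truth columns
#'   `true_subtype`, `true_stage` and `true_cdp_time`.
#' @export
simulate_patients <- function(config, n, n_datasets = 3, n_visits = 3,
                              visit_spacing = 1, sim_noise = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  C <- config$n_subtypes
  if (n < C) stop("need at least as many patients as subtypes")
  if (n_datasets < 1 || n_visits < 1) stop("n_datasets and n_visits must be >= 1")
  if (n * n_visits > 5e6) stop("requested table exceeds the configured cap")
  if (is.null(sim_noise)) sim_noise <- config$sim_noise
  grid <- config$grid
  E <- grid$E
  flip <- config$features %in% flip_features(config$features)
  aff_idx <- match(config$affected, config$features)

  local_seed(config$seed + 2L, {
    subtype <- sample.int(C, n, replace = TRUE, prob = config$fractions)
    stage0 <- numeric(n)
    for (c in seq_len(C)) {
      idx <- which(subtype == c)
      stage0[idx] <- sample(0:E, length(idx), replace = TRUE,
                            prob = stage_probs(config$stage_mean[c], E))
    }
    # per-subject phase dither so that rounding to integer stages is
    # unbiased: subjects cross stage boundaries at different times
    phase <- stats::runif(n, -0.5, 0.5)
    cov <- draw_covariates(n, patient = TRUE)
    dataset <- rep_len(seq_len(n_datasets), n)
    arm <- ifelse(stats::runif(n) < 0.5, "placebo", "treated")
    tx_mult <- ifelse(arm == "treated",
                      config$treatment_multiplier[subtype], 1)
    # latent disability-progression time (years): exponential with the
    # subtype's placebo hazard; treatment thins the event with probability
    # 1 - multiplier, so the treated step process is exactly the placebo
    # process scaled by the multiplier
    cdp_time <- stats::rexp(n, rate = config$cdp_hazard[subtype])
    cdp_time[stats::runif(n) > tx_mult] <- Inf
    edss0 <- config$edss_base + config$edss_stage_coef * stage0 +
      config$edss_subtype_offset[subtype]
    # trajectories per subtype, F_aff x (E+1)
    Gs <- lapply(config$sequences, function(s) event_trajectory(grid, s))

    rows <- vector("list", n_visits)
    offsets <- rep_len(config$dataset_offsets, n_datasets)
    for (v in seq_len(n_visits)) {
      t_v <- (v - 1) * visit_spacing
      stage_v <- pmin(E, pmax(0, round(
        stage0 + config$progression_rate[subtype] * t_v + phase)))
      if (v == 1) stage_v <- stage0     # baseline stage is the drawn stage
      zmat <- matrix(0, n, length(config$affected))
      for (c in seq_len(C)) {
        idx <- which(subtype == c)
        zmat[idx, ] <- t(Gs[[c]][, stage_v[idx] + 1, drop = FALSE])
      }
      cov_v <- cov
      cov_v$age <- cov$age + t_v
      mu <- normative_mean(config, cov_v)
      feat <- mu
      # planted abnormality on affected features (sign by flip convention)
      dir <- ifelse(flip[aff_idx], -1, 1)
      shift <- sweep(zmat, 2, config$control_sd[aff_idx] * dir, `*`)
      feat[, aff_idx] <- feat[, aff_idx] + shift
      # residual noise (z-scale sim_noise on every feature) + dataset offset
      eps <- matrix(stats::rnorm(n * ncol(mu)), n) %*%
        diag(sim_noise * config$control_sd, ncol(mu))
      feat <- feat + eps
      feat <- feat + outer(offsets[dataset], config$control_sd)
      colnames(feat) <- config$features

      slope <- config$edss_slope[subtype] * tx_mult
      progressed <- t_v >= cdp_time & t_v > 0
      step <- ifelse(progressed,
                     edss_step_size(round_half(pmin(10, pmax(0, edss0)))), 0)
      edss <- edss0 + slope * t_v + step +
        stats::rnorm(n, 0, config$edss_noise_sd)
      edss <- round_half(pmin(10, pmax(0, edss)))
      relapses <- if (v == 1) rep(NA_integer_, n) else
        stats::rpois(n, config$relapse_rate[subtype] * tx_mult * visit_spacing)
      gad <- stats::rpois(n, config$gad_rate[subtype] *
                            ifelse(arm == "treated", tx_mult, 1))
      rows[[v]] <- data.frame(
        subject_id = sprintf("MS%05d", seq_len(n)),
        dataset_id = sprintf("trial%02d", dataset),
        arm = arm, visit_time = t_v,
        age = cov_v$age, sex = cov$sex, tiv = cov$tiv,
        feat, edss = edss, relapses_since_last_visit = relapses,
        gad_count = gad, true_subtype = subtype, true_stage = stage_v,
        true_cdp_time = cdp_time, check.names = FALSE
      )
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$subject_id, out$visit_time), ]
    rownames(out) <- NULL
    as_cohort_table(out)
  })
}

# EDSS step planted at the progression event: the required increase for the
# subject's baseline score plus a margin so confirmation survives rounding
edss_step_size <- function(baseline_edss) {
  edss_increase_threshold(baseline_edss) + 0.25
}

#' Packaged synthetic fixture
#'
#' The default configuration ([default_config()]) together with a control
#' table (n = 500, one visit) and a patient table (n = 2000, three
#' pseudo-trials, three annual visits), all derived from the stored master
#' seed so the fixture regenerates identically.
#'
#' @param seed master seed (default the configuration's stored seed).
#' @return List with elements `config`, `controls`, `patients`.
#' @export
default_fixture <- function(seed = 20260925L) {
  config <- default_config(seed)
  list(config = config,
       controls = simulate_controls(config, 500),
       patients = simulate_patients(config, 2000, n_datasets = 3, n_visits = 3))
}
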