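# End-to-end orchestration: simulate -> z-score -> select -> fit/cv ->
# stage -> endpoints, with JSON serialization and a reproducibility
# manifest.

#' Pipeline configuration
#'
#' Collects the run-level constants: the effect-size threshold (0.5),
#' z-score event thresholds (1, 2, 3), the asymptote z_max (5), the
#' 24-week confirmation window, the candidate subtype range, MCMC
#' settings, the execution profile and the master seed. The `test`
#' profile uses the reduced simulator ([small_config()]: 8 features, 24
#' events, 600 patients, 3 pseudo-trials) and 10,000 MCMC iterations; the
#' `full` profile uses the default fixture scale and 100,000 iterations.
#'
#' @param out_dir output directory.
#' @param profile `"test"` or `"full"`.
#' @param seed master seed.
#' @param n_subtypes fixed subtype count, or NULL to select by
#'   cross-validation.
#' @param candidates candidate subtype counts for CV.
#' @param d_threshold Cohen's D feature-selection threshold.
#' @param thresholds z-score event thresholds.
#' @param z_max trajectory asymptote.
#' @param confirm_weeks CDP confirmation window in weeks.
#' @param mcmc_iterations MCMC iterations (NULL: profile default).
#' @param n_starts,max_em fitting effort (NULL: profile default).
#' @param validation_datasets dataset ids to hold out from training; the
#'   frozen trained model is applied to them for staging only.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, profile = c("test", "full"),
                            seed = 1L, n_subtypes = NULL, candidates = 1:4,
                            d_threshold = 0.5, thresholds = c(1, 2, 3),
                            z_max = 5, confirm_weeks = 24,
                            mcmc_iterations = NULL, n_starts = NULL,
                            max_em = NULL, validation_datasets = NULL) {
  profile <- match.arg(profile)
  if (d_threshold <= 0 || z_max <= 0 || confirm_weeks <= 0)
    stop("thresholds must be positive")
  if (is.null(mcmc_iterations))
    mcmc_iterations <- if (profile == "test") 1e4 else 1e5
  if (is.null(n_starts)) n_starts <- if (profile == "test") 3 else 25
  if (is.null(max_em)) max_em <- if (profile == "test") 15 else 100
  structure(list(
    out_dir = out_dir, profile = profile, seed = as.integer(seed),
    n_subtypes = n_subtypes, candidates = candidates,
    d_threshold = d_threshold, thresholds = thresholds, z_max = z_max,
    confirm_weeks = confirm_weeks, mcmc_iterations = mcmc_iterations,
    n_starts = n_starts, max_em = max_em,
    validation_datasets = validation_datasets
  ), class = "pipeline_config")
}

#' Serialize a fitted model to JSON
#'
#' @param model a `sustain` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sustain <- function(model, path) {
  obj <- list(
    features = model$grid$features,
    thresholds = model$grid$thresholds,
    z_max = as.numeric(model$grid$z_max),
    sequences = lapply(model$sequences, as.integer),
    fractions = as.numeric(model$f),
    sigma = as.numeric(model$sigma),
    logLik = model$logLik, k = model$k, n = model$n
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path file written by [write_sustain()].
#' @return A `sustain` object (without responsibilities).
#' @export
read_sustain <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- event_grid(obj$features, obj$thresholds, obj$z_max)
  seqs <- obj$sequences
  if (is.matrix(seqs)) seqs <- lapply(seq_len(nrow(seqs)), function(i) seqs[i, ])
  seqs <- lapply(seqs, as.integer)
  for (s in seqs) check_sequence(s, grid)
  structure(list(
    grid = grid, sequences = seqs, f = obj$fractions,
    sigma = stats::setNames(obj$sigma, grid$features),
    logLik = obj$logLik, k = obj$k, n = obj$n
  ), class = "sustain")
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the cohorts, fits the normative model on
#' controls, z-scores the patients, selects features by effect size, fits
#' the subtype model (at a fixed C or by leave-one-dataset-out CV),
#' samples the sequence posterior, stages every visit, and computes the
#' clinical endpoint report. When `validation_datasets` are configured,
#' those datasets are excluded from training and staged with the frozen
#' model. All outputs are written under `config$out_dir` and listed, with
#' checksums and per-stage wall times, in the returned manifest.
#'
#' @param config a [pipeline_config()].
#' @param controls,patients optional pre-built cohort tables; simulated
#'   per profile when omitted.
#' @return The run manifest (list), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, controls = NULL, patients = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t_all <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    t_all[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  set.seed(config$seed)

  sim_cfg <- NULL
  if (is.null(controls) || is.null(patients)) {
    sim_cfg <- if (config$profile == "test")
      small_config(config$seed) else default_config(config$seed)
    controls <- tick("simulate_controls",
                     simulate_controls(sim_cfg, if (config$profile == "test") 200 else 500))
    patients <- tick("simulate_patients",
                     simulate_patients(sim_cfg,
                                       if (config$profile == "test") 600 else 2000,
                                       n_datasets = 3, n_visits = 3))
    write_cohort(controls, file.path(config$out_dir, "controls.csv"))
    write_cohort(patients, file.path(config$out_dir, "patients.csv"))
    sidecar <- list(seed = sim_cfg$seed, fractions = sim_cfg$fractions,
                    affected = sim_cfg$affected,
                    sequences = lapply(sim_cfg$sequences, as.integer),
                    progression_rate = sim_cfg$progression_rate)
    write_json_report(sidecar, file.path(config$out_dir, "ground_truth.json"))
  }

  nm <- tick("normative", fit_normative(controls))
  sel <- tick("select_features",
              select_features(controls, patients, model = nm,
                              threshold = config$d_threshold))
  feats <- attr(sel, "retained")

  train <- patients
  valid <- NULL
  if (!is.null(config$validation_datasets)) {
    valid <- patients[patients$dataset_id %in% config$validation_datasets, ]
    train <- patients[!patients$dataset_id %in% config$validation_datasets, ]
    if (!nrow(train)) stop("validation split leaves no training data")
  }
  z_train <- tick("zscore", compute_zscores(train, nm, features = feats))
  write_cohort(z_train, file.path(config$out_dir, "zscores_train.csv"))

  if (is.null(config$n_subtypes)) {
    cv <- tick("cv", cv_sustain(z_train, candidates = config$candidates,
                                seed = config$seed,
                                thresholds = config$thresholds,
                                z_max = config$z_max,
                                n_starts = config$n_starts,
                                max_em = config$max_em))
    model <- cv$model
    utils::write.csv(cv$heldout,
                     file.path(config$out_dir, "cv_heldout_loglik.csv"))
  } else {
    cv <- NULL
    model <- tick("fit", sustain(z_train, k = config$n_subtypes,
                                 thresholds = config$thresholds,
                                 z_max = config$z_max,
                                 n_starts = config$n_starts,
                                 max_em = config$max_em,
                                 seed = config$seed))
  }
  model_path <- file.path(config$out_dir, "model.json")
  write_sustain(model, model_path)

  mcmc <- tick("mcmc", sustain_mcmc(model, z_train,
                                    iterations = config$mcmc_iterations,
                                    seed = config$seed))

  asg <- tick("stage", predict(model, z_train))
  write_cohort(asg, file.path(config$out_dir, "assignments_train.csv"))
  if (!is.null(valid) && nrow(valid)) {
    frozen <- read_sustain(model_path)        # staging never refits
    z_val <- compute_zscores(valid, nm, features = feats)
    asg_val <- predict(frozen, z_val)
    write_cohort(asg_val, file.path(config$out_dir, "assignments_validation.csv"))
  }

  ep <- tick("endpoints", endpoint_report(train, asg,
                                          confirm_days = config$confirm_weeks * 7))
  write_json_report(ep, file.path(config$out_dir, "endpoints.json"))

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest[.]json$", outputs)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("sustainMS")),
    profile = config$profile, seed = config$seed,
    selected_subtypes = model$k,
    config_hash = unname(tools::md5sum(local({
      p <- file.path(config$out_dir, "config.json")
      write_json_report(unclass(config), p); p
    }))),
    stage_seconds = t_all,
    outputs = data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)))
  )
  write_json_report(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}

#' Clinical endpoint report for an assigned cohort
#'
#' Joins per-visit subtype/stage assignments to the cohort and computes
#' the endpoint battery: per-subtype CDP survival contrasts (Cox hazard
#' ratios against subtype 1 and the k-group log-rank test, placebo arms),
#' annualised relapse rates, stage-tertile survival, annual stage change
#' in placebo arms, subtype stability, and the concordance of baseline
#' stage for CDP.
#'
#' @param cohort patient `cohort_table`.
#' @param assignments per-visit output of [predict.sustain()] (rows
#'   aligned with `cohort` or carrying `subject_id`/`visit_time` keys).
#' @param confirm_days CDP confirmation window in days.
#' @return List of endpoint tables.
#' @export
endpoint_report <- function(cohort, assignments, confirm_days = 168) {
  stopifnot(nrow(cohort) == nrow(assignments) ||
              all(c("subject_id", "visit_time") %in% names(assignments)))
  if (nrow(cohort) == nrow(assignments) &&
      !all(c("subject_id", "visit_time") %in% names(assignments))) {
    assignments <- cbind(cohort[, c("subject_id", "visit_time")], assignments)
  }
  base_asg <- baseline_subtypes(assignments)
  placebo <- cohort[cohort$arm == "placebo", ]

  surv <- cdp_survival(placebo, groups = base_asg,
                       confirm_days = confirm_days)
  surv$group <- paste0("subtype", surv$subtype)
  lr <- try(logrank_compare(surv), silent = TRUE)
  hr <- try(hazard_contrast(surv, reference = "subtype1"), silent = TRUE)

  tert <- stage_tertiles(base_asg$baseline_stage)
  tert_groups <- data.frame(subject_id = base_asg$subject_id,
                            group = tert$group)
  surv_t <- cdp_survival(placebo, groups = tert_groups,
                         confirm_days = confirm_days)
  lr_t <- try(logrank_compare(surv_t), silent = TRUE)

  arr <- annualized_relapse_rate(
    placebo, data.frame(subject_id = base_asg$subject_id,
                        group = paste0("subtype", base_asg$subtype)))
  asc <- annual_stage_change(
    merge(assignments,
          unique(cohort[cohort$arm == "placebo", "subject_id", drop = FALSE]),
          by = "subject_id"),
    data.frame(subject_id = base_asg$subject_id,
               group = paste0("subtype", base_asg$subtype)))
  tr <- try(treatment_response(cohort, base_asg[, c("subject_id", "subtype")]),
            silent = TRUE)
  surv_stage <- merge(cdp_survival(placebo, confirm_days = confirm_days),
                      base_asg[, c("subject_id", "baseline_stage")],
                      by = "subject_id")
  ci <- concordance_index(surv_stage$baseline_stage, surv_stage$time,
                          surv_stage$event)

  list(
    logrank_subtypes = if (inherits(lr, "try-error")) NULL else lr,
    hazard_ratios = if (inherits(hr, "try-error")) NULL else hr,
    logrank_stage_tertiles = if (inherits(lr_t, "try-error")) NULL else lr_t,
    tertile_cuts = tert$cuts,
    relapse_rates = arr,
    annual_stage_change = asc,
    treatment_response = if (inherits(tr, "try-error")) NULL else tr,
    concordance_baseline_stage = ci,
    subtype_stability = subtype_stability(assignments)
  )
}

# per-subject modal subtype and stage at the baseline visit
baseline_subtypes <- function(assignments) {
  ord <- order(assignments$subject_id, assignments$visit_time)
  a <- assignments[ord, ]
  a <- a[!duplicated(a$subject_id), ]
  data.frame(subject_id = a$subject_id, subtype = a$subtype,
             baseline_stage = a$stage_mode)
}
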