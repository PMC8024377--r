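#' Ground-truth configuration for the synthetic cohort simulator
#'
#' Bundles every parameter of the generative model that the simulator
#' realises: the control-stratum feature distributions and covariate
#' effects, the latent subtype structure (event sequences, mixture
#' fractions, stage distributions, progression rates), dataset-level
#' offsets for the pseudo-trials, and the coupling of clinical outcomes
#' (EDSS, relapses, contrast-enhancing lesions, disability progression,
#' treatment effect) to subtype and stage.
#'
#' @param features character vector of feature names.
#' @param affected subset of `features` that carry planted abnormality
#'   trajectories; the rest follow the control law in patients too.
#' @param sequences list of C integer permutations of `1:E` where
#'   `E = length(affected) * length(thresholds)`; events are indexed
#'   feature-major (all thresholds of the first affected feature, then the
#'   second, ...). Each sequence must respect the within-feature threshold
#'   order.
#' @param fractions mixture weights over subtypes (sum to 1).
#' @param thresholds z-score event thresholds, default `c(1, 2, 3)`.
#' @param z_max asymptotic abnormality level after the last event.
#' @param stage_mean per-subtype mean of the truncated-geometric baseline
#'   stage distribution.
#' @param progression_rate per-subtype stage advance in stages/year.
#' @param control_mean,control_sd per-feature location and residual scale
#'   of the control stratum (raw units).
#' @param covariate_coefs F x 4 matrix of per-feature coefficients for
#'   (tiv, sex, age, age^2).
#' @param dataset_offsets per-pseudo-trial additive shift, in units of
#'   `control_sd`, applied to all features of patients in that dataset.
#' @param sim_noise residual SD of patient features around the planted
#'   trajectory, on the z-score scale.
#' @param edss_base,edss_stage_coef,edss_subtype_offset baseline EDSS model:
#'   `edss0 = edss_base + edss_stage_coef * stage + offset[subtype] + noise`.
#' @param edss_slope per-subtype placebo EDSS worsening, points/year.
#' @param edss_noise_sd EDSS measurement noise SD before rounding to the
#'   half-point lattice.
#' @param relapse_rate per-subtype annualised relapse rate (placebo).
#' @param gad_rate per-subtype mean contrast-enhancing lesion count.
#' @param cdp_hazard per-subtype hazard (1/years) of the latent disability
#'   progression event in the placebo arm.
#' @param treatment_multiplier per-subtype multiplier applied on treatment
#'   to the EDSS slope, the relapse rate and the progression hazard.
#' @param seed master seed; sub-streams are derived by fixed offsets.
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [default_config()], [simulate_controls()], [simulate_patients()]
#' @export
cohort_config <- function(features, affected, sequences, fractions,
                          thresholds = c(1, 2, 3), z_max = 5,
                          stage_mean, progression_rate,
                          control_mean, control_sd, covariate_coefs,
                          dataset_offsets = c(0, 0.1, -0.1),
                          sim_noise = 0.25,
                          edss_base = 2, edss_stage_coef = 0.1,
                          edss_subtype_offset = NULL,
                          edss_slope = NULL, edss_noise_sd = 0.15,
                          relapse_rate = NULL, gad_rate = NULL,
                          cdp_hazard = NULL, treatment_multiplier = NULL,
                          seed = 1L) {
  C <- length(sequences)
  F_all <- length(features)
  E <- length(affected) * length(thresholds)
  if (is.null(edss_subtype_offset)) edss_subtype_offset <- rep(0, C)
  if (is.null(edss_slope)) edss_slope <- rep(0.1, C)
  if (is.null(relapse_rate)) relapse_rate <- rep(0.3, C)
  if (is.null(gad_rate)) gad_rate <- rep(1, C)
  if (is.null(cdp_hazard)) cdp_hazard <- rep(0.2, C)
  if (is.null(treatment_multiplier)) treatment_multiplier <- rep(1, C)

  stopifnot(
    length(affected) <= F_all, all(affected %in% features),
    length(fractions) == C, length(stage_mean) == C,
    length(progression_rate) == C, all(progression_rate >= 0),
    length(control_mean) == F_all, length(control_sd) == F_all,
    all(control_sd > 0), is.matrix(covariate_coefs),
    nrow(covariate_coefs) == F_all, ncol(covariate_coefs) == 4
  )
  if (abs(sum(fractions) - 1) > 1e-12)
    stop("mixture fractions must sum to 1 (got ", sum(fractions), ")")
  for (s in sequences) {
    if (length(s) != E || !setequal(s, seq_len(E)))
      stop("each sequence must be a permutation of 1:", E)
  }
  grid <- event_grid(affected, thresholds, z_max)
  for (s in sequences) check_sequence(s, grid)

  structure(list(
    features = features, affected = affected, n_subtypes = C,
    sequences = sequences, fractions = fractions,
    thresholds = thresholds, z_max = z_max,
    stage_mean = stage_mean, progression_rate = progression_rate,
    control_mean = stats::setNames(control_mean, features),
    control_sd = stats::setNames(control_sd, features),
    covariate_coefs = covariate_coefs,
    dataset_offsets = dataset_offsets, sim_noise = sim_noise,
    edss_base = edss_base, edss_stage_coef = edss_stage_coef,
    edss_subtype_offset = edss_subtype_offset, edss_slope = edss_slope,
    edss_noise_sd = edss_noise_sd, relapse_rate = relapse_rate,
    gad_rate = gad_rate, cdp_hazard = cdp_hazard,
    treatment_multiplier = treatment_multiplier,
    grid = grid, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  features: ", length(x$features), " (", length(x$affected),
      " affected; E = ", x$grid$E, " events)\n", sep = "")
  cat("  subtypes: ", x$n_subtypes, "; fractions ",
      paste(format(x$fractions), collapse = " / "), "\n", sep = "")
  cat("  progression rates (stages/yr): ",
      paste(format(x$progression_rate), collapse = " / "), "\n", sep = "")
  cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

# Build a valid sequence from a per-feature priority order: event (i, z)
# gets key rank(i) + spread * (z - 1); sorting keys staggers thresholds so
# early features reach severe abnormality while late features begin, and the
# within-feature threshold order holds because the key increases with z.
sequence_from_priority <- function(priority, n_thresholds = 3, spread = NULL) {
  F_aff <- length(priority)
  if (is.null(spread)) spread <- ceiling(F_aff * 0.55)
  ev_feature <- rep(seq_len(F_aff), each = n_thresholds)
  ev_z <- rep(seq_len(n_thresholds), times = F_aff)
  rank <- match(ev_feature, priority)
  key <- rank + spread * (ev_z - 1)
  order(key, rank, ev_z)
}

#' Default ground-truth configuration (fixture G1)
#'
#' The packaged stand-in for a multi-trial MS cohort: 18 canonical MRI
#' features of which 13 are affected, three latent subtypes whose event
#' sequences echo the cortex-led / NAWM-led / lesion-led orderings
#' (early cortical atrophy, early corpus-callosum and cingulate T1/T2
#' reduction, and early lesion accrual with deep grey matter atrophy,
#' respectively), mixture fractions 0.43/0.32/0.25, and clinical coupling
#' with an elevated relapse rate, progression hazard and a strong
#' treatment effect in the lesion-led subtype.
#'
#' Control means and SDs are plausible adult values in ml (volumes) and
#' unitless ratios; they are documented constants of the simulator, not
#' estimates from any real cohort.
#'
#' @param seed master seed (default 20260925).
#' @return A [cohort_config()] object.
#' @export
default_config <- function(seed = 20260925L) {
  md <- feature_metadata()
  features <- md$feature
  affected <- c("gmv_frontal", "gmv_parietal", "gmv_temporal", "gmv_occipital",
                "gmv_limbic", "gmv_deep",
                "t1t2_cc", "t1t2_cingulate", "t1t2_temporal", "t1t2_parietal",
                "t1t2_occipital", "t1t2_cerebellum", "lesion_load")

  ctrl <- rbind(
    gmv_frontal     = c(165,  8.0), gmv_parietal   = c(115, 6.0),
    gmv_temporal    = c(130,  7.0), gmv_occipital  = c(70,  5.0),
    gmv_limbic      = c(42,   3.0), gmv_cerebellum = c(105, 7.0),
    gmv_deep        = c(33,   1.6), wmv_cerebral   = c(470, 25.0),
    wmv_cerebellum  = c(26,   2.4), vol_brainstem  = c(24,  1.8),
    lesion_load     = c(1.2,  1.0), t1t2_cc        = c(1.90, 0.09),
    t1t2_frontal    = c(1.75, 0.08), t1t2_temporal = c(1.70, 0.08),
    t1t2_parietal   = c(1.78, 0.08), t1t2_occipital = c(1.72, 0.08),
    t1t2_cingulate  = c(1.85, 0.09), t1t2_cerebellum = c(1.60, 0.08)
  )
  ctrl <- ctrl[features, , drop = FALSE]

  # covariate effects (tiv ml, sex 0/1, age yr, age^2): volumes scale with
  # head size and shrink with age; ratios drift slightly with age only
  is_vol <- md$kind == "volume"
  coefs <- cbind(
    tiv  = ifelse(is_vol, ctrl[, 1] / 20000, 0),
    sex  = ifelse(is_vol, -ctrl[, 1] / 120, 0.005),
    age  = ifelse(is_vol, -ctrl[, 1] / 1500, -0.002),
    age2 = ifelse(is_vol, -ctrl[, 1] / 3e5, -5e-6)
  )
  rownames(coefs) <- features
  coefs["lesion_load", ] <- c(0, 0, 0.003, 0)

  pri <- list(
    cortex = c("gmv_occipital", "gmv_parietal", "gmv_frontal", "gmv_temporal",
               "gmv_limbic", "gmv_deep", "lesion_load", "t1t2_parietal",
               "t1t2_temporal", "t1t2_cerebellum", "t1t2_occipital",
               "t1t2_cc", "t1t2_cingulate"),
    nawm = c("t1t2_cc", "t1t2_cingulate", "t1t2_cerebellum", "t1t2_temporal",
             "t1t2_parietal", "gmv_occipital", "lesion_load", "t1t2_occipital",
             "gmv_parietal", "gmv_frontal", "gmv_temporal", "gmv_limbic",
             "gmv_deep"),
    lesion = c("lesion_load", "gmv_deep", "gmv_occipital", "gmv_parietal",
               "gmv_temporal", "gmv_frontal", "gmv_limbic", "t1t2_cc",
               "t1t2_cingulate", "t1t2_temporal", "t1t2_parietal",
               "t1t2_occipital", "t1t2_cerebellum")
  )
  sequences <- lapply(pri, function(p)
    sequence_from_priority(match(p, affected), n_thresholds = 3, spread = 7))

  cohort_config(
    features = features, affected = affected, sequences = sequences,
    fractions = c(0.43, 0.32, 0.25),
    stage_mean = c(14.5, 13.8, 16.2),
    progression_rate = c(0.2, 0.3, 0.65),
    control_mean = ctrl[, 1], control_sd = ctrl[, 2],
    covariate_coefs = coefs,
    dataset_offsets = c(0, 0.1, -0.1),
    sim_noise = 0.25,
    edss_base = 2, edss_stage_coef = 0.1,
    edss_subtype_offset = c(0, -0.3, 0.4),
    edss_slope = c(0.06, 0.08, 0.10), edss_noise_sd = 0.15,
    relapse_rate = c(0.25, 0.25, 0.55),
    gad_rate = c(0.9, 0.5, 2.3),
    cdp_hazard = c(0.20, 0.20, 0.26),
    treatment_multiplier = c(1, 1, 0.34),
    seed = seed
  )
}

#' Reduced configuration for fast experimentation
#'
#' Eight affected features (24 events) and three subtypes; the same
#' generative mechanics as [default_config()] at a fraction of the cost.
#'
#' @param seed master seed.
#' @return A [cohort_config()] object.
#' @export
small_config <- function(seed = 20260925L) {
  features <- paste0("f", 1:8)
  ctrl_mean <- c(100, 80, 60, 40, 30, 1.9, 1.8, 2)
  ctrl_sd <- c(6, 5, 4, 3, 2, 0.09, 0.08, 1)
  coefs <- cbind(tiv = c(rep(0.004, 5), 0, 0, 0),
                 sex = c(rep(-0.5, 5), 0, 0, 0),
                 age = rep(-0.01, 8), age2 = rep(0, 8))
  pri <- list(s1 = 1:8, s2 = c(6, 7, 8, 1, 2, 3, 4, 5), s3 = c(8, 5, 4, 3, 2, 1, 6, 7))
  sequences <- lapply(pri, sequence_from_priority, n_thresholds = 3, spread = 4)
  cohort_config(
    features = features, affected = features, sequences = sequences,
    fractions = c(0.4, 0.35, 0.25),
    stage_mean = c(9, 8, 10), progression_rate = c(0.2, 0.3, 0.65),
    control_mean = ctrl_mean, control_sd = ctrl_sd,
    covariate_coefs = coefs, dataset_offsets = c(0, 0.1, -0.1),
    sim_noise = 0.25,
    edss_subtype_offset = c(0, -0.3, 0.4),
    edss_slope = c(0.06, 0.08, 0.10),
    relapse_rate = c(0.25, 0.25, 0.55), gad_rate = c(0.9, 0.5, 2.3),
    cdp_hazard = c(0.20, 0.20, 0.26), treatment_multiplier = c(1, 1, 0.34),
    seed = seed
  )
}
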