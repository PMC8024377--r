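# Control-referenced normative modelling and z-scoring.
#
# Each MRI feature is regressed on total intracranial volume, sex, age and
# age squared in healthy controls; patients' visits are expressed as
# z-scores of the covariate-adjusted residual relative to the control
# residual distribution, sign-corrected so that higher z means worse.

normative_design <- function(x) {
  cbind(intercept = 1, tiv = x$tiv, sex = x$sex, age = x$age, age2 = x$age^2)
}

#' Fit the normative control model
#'
#' Per-feature linear regression of the raw value on (tiv, sex, age,
#' age^2) in controls. The point fit is the posterior mean under a flat
#' prior, i.e. ordinary least squares; residual SDs use denominator n - 5
#' (five regression parameters).
#'
#' @param controls a control `cohort_table` (>= 10 visits).
#' @param features feature columns to model (default: every canonical
#'   feature present in `controls`).
#' @return An object of class `normative_model`: coefficient matrix
#'   (5 x F), per-feature residual SD, adjusted control mean (mean control
#'   residual, identically ~0 for OLS with intercept), and the control
#'   count.
#' @export
fit_normative <- function(controls, features = NULL) {
  if (is.null(features)) features <- intersect(ms_features(), names(controls))
  if (!length(features)) features <- setdiff(names(controls),
    c(cohort_key_cols, "edss", "relapses_since_last_visit", "gad_count",
      "true_subtype", "true_stage", "true_cdp_time"))
  if (nrow(controls) < 10) stop("need at least 10 control visits")
  X <- normative_design(controls)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient covariate design (degenerate tiv/sex/age)")
  Y <- as.matrix(controls[, features, drop = FALSE])
  if (nrow(X) <= ncol(X)) stop("fewer controls than regression parameters")
  fit <- stats::lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  sds <- sqrt(colSums(res^2) / (nrow(X) - ncol(X)))
  if (any(sds <= 0))
    warning("zero control residual SD for: ",
            paste(features[sds <= 0], collapse = ", "),
            " (z-scores for these features are undefined)")
  structure(list(
    features = features,
    coefficients = fit$coefficients,
    residual_sd = stats::setNames(sds, features),
    control_mean_residual = stats::setNames(colMeans(res), features),
    n_controls = nrow(X)
  ), class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("Normative model: ", length(x$features), " features fit on ",
      x$n_controls, " controls (value ~ tiv + sex + age + age^2)\n", sep = "")
  invisible(x)
}

#' @export
predict.normative_model <- function(object, newdata, ...) {
  X <- normative_design(newdata)
  P <- X %*% object$coefficients
  colnames(P) <- object$features
  P
}

#' Compute sign-corrected z-scores
#'
#' z = (patient residual - mean control residual) / control residual SD,
#' then negated for features in `flip` so that abnormality (atrophy, lower
#' T1/T2 ratio) is positive; lesion volume, which worsens upward, is not
#' flipped.
#'
#' @param cohort a `cohort_table` with covariates and feature columns.
#' @param model a [fit_normative()] model covering all requested features.
#' @param features features to score (default: all model features).
#' @param flip features whose sign is inverted; defaults to the canonical
#'   convention of [feature_metadata()] (volumes and ratios flipped,
#'   lesion volume not).
#' @return A `zscore_table`: data.frame with the key columns of `cohort`
#'   followed by one z-score column per feature; attributes `features` and
#'   `flipped` record the scored set and the sign convention.
#' @export
compute_zscores <- function(cohort, model, features = model$features,
                            flip = NULL) {
  missing_f <- setdiff(features, model$features)
  if (length(missing_f))
    stop("features absent from normative model: ",
         paste(missing_f, collapse = ", "))
  if (any(model$residual_sd[features] <= 0))
    stop("zero control residual SD for: ",
         paste(features[model$residual_sd[features] <= 0], collapse = ", "))
  if (is.null(flip)) flip <- flip_features(features)
  P <- predict(model, cohort)[, features, drop = FALSE]
  resid <- as.matrix(cohort[, features, drop = FALSE]) - P
  z <- sweep(resid, 2, model$control_mean_residual[features], `-`)
  z <- sweep(z, 2, model$residual_sd[features], `/`)
  z[, colnames(z) %in% flip] <- -z[, colnames(z) %in% flip]
  keep <- intersect(c(cohort_key_cols, "true_subtype", "true_stage"),
                    names(cohort))
  out <- cbind(cohort[, keep, drop = FALSE], as.data.frame(z))
  rownames(out) <- NULL
  structure(out, features = features, flipped = intersect(features, flip),
            class = c("zscore_table", "data.frame"))
}

# numeric z matrix from a zscore_table (or pass-through for matrices)
zscore_matrix <- function(z, features = NULL) {
  if (is.matrix(z)) return(z)
  if (is.null(features)) features <- attr(z, "features")
  if (is.null(features)) stop("cannot identify feature columns")
  as.matrix(z[, features, drop = FALSE])
}

#' Cohen's D effect size
#'
#' Standardised mean difference `(mean_b - mean_a) / s_pooled` with the
#' pooled SD `sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param group_a,group_b numeric samples (>= 2 observations each).
#' @return The effect size (positive when `group_b` has the larger mean).
#' @export
cohen_d <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 observations")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  (mean(group_b) - mean(group_a)) / sqrt(sp2)
}

#' Select features by patient-versus-control effect size
#'
#' Computes per-feature Cohen's D between covariate-adjusted control
#' values and covariate-adjusted patient baseline values and retains
#' features with |D| above the threshold (default 0.5, a moderate
#' effect). When both a region's grey-matter volume and its white-matter
#' T1/T2 ratio pass, the volume is kept for grey-matter regions and the
#' ratio for white-matter regions (the two are strongly correlated within
#' region); concretely, a passing white-matter volume is dropped whenever
#' the same region's ratio also passes.
#'
#' @param controls control `cohort_table`.
#' @param patients patient `cohort_table`; restricted internally to each
#'   subject's baseline (earliest) visit.
#' @param model optional pre-fit [fit_normative()] model (fitted on
#'   `controls` if omitted).
#' @param threshold |D| cutoff, default 0.5.
#' @param metadata feature metadata for region arbitration; defaults to
#'   [feature_metadata()]. Features absent from it skip arbitration.
#' @return An object of class `feature_selection`: data.frame of per-
#'   feature D values with the retained flag, plus attributes `retained`
#'   and `threshold`.
#' @export
select_features <- function(controls, patients, model = NULL,
                            threshold = 0.5, metadata = feature_metadata()) {
  if (is.null(model)) model <- fit_normative(controls)
  features <- model$features
  base <- baseline_visits(patients)
  adj_c <- as.matrix(controls[, features, drop = FALSE]) -
    predict(model, controls)[, features, drop = FALSE]
  adj_p <- as.matrix(base[, features, drop = FALSE]) -
    predict(model, base)[, features, drop = FALSE]
  d <- vapply(features, function(f) cohen_d(adj_c[, f], adj_p[, f]),
              numeric(1))
  pass <- abs(d) > threshold
  retained <- features[pass]
  # region arbitration: drop white-matter volumes shadowed by their ratio
  md <- metadata[match(retained, metadata$feature), , drop = FALSE]
  drop <- rep(FALSE, length(retained))
  for (k in seq_along(retained)) {
    if (is.na(md$feature[k])) next
    if (md$kind[k] == "volume" && md$tissue[k] == "wm") {
      twin <- metadata$feature[metadata$region == md$region[k] &
                                 metadata$kind == "ratio"]
      if (length(twin) && any(twin %in% retained)) drop[k] <- TRUE
    }
  }
  retained <- retained[!drop]
  if (!length(retained))
    stop("no features pass |D| > ", threshold, "; observed D: ",
         paste(sprintf("%s=%.3f", features, d), collapse = ", "))
  tab <- data.frame(feature = features, cohen_d = d,
                    retained = features %in% retained, row.names = NULL)
  structure(tab, retained = retained, threshold = threshold,
            class = c("feature_selection", "data.frame"))
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("Feature selection: ", length(attr(x, "retained")), "/", nrow(x),
      " features with |D| > ", attr(x, "threshold"), "\n", sep = "")
  NextMethod()
}
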