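# Leave-one-dataset-out cross-validation for choosing the number of
# subtypes, and Bhattacharyya agreement of sequence posteriors across folds.

#' Leave-one-dataset-out fold specification
#'
#' One fold per dataset id: the fold's model is trained on every other
#' dataset and evaluated on the held-out one. Folds are ordered
#' deterministically by dataset id.
#'
#' @param dataset_id vector of dataset labels (one per visit), or a
#'   `cohort_table`/`zscore_table` with a `dataset_id` column.
#' @return An object of class `fold_spec`: list of
#'   `list(train = ids, test = id)`, one per dataset.
#' @export
split_by_dataset <- function(dataset_id) {
  if (is.data.frame(dataset_id)) dataset_id <- dataset_id$dataset_id
  ids <- sort(unique(as.character(dataset_id)))
  if (length(ids) < 2)
    stop("leave-one-dataset-out requires at least 2 datasets")
  folds <- lapply(ids, function(id) list(train = setdiff(ids, id), test = id))
  structure(folds, ids = ids, class = "fold_spec")
}

#' @export
print.fold_spec <- function(x, ...) {
  cat("Leave-one-dataset-out folds: ", length(x), " datasets (",
      paste(attr(x, "ids"), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Select the number of subtypes by cross-validated log-likelihood
#'
#' For every fold and every candidate subtype count C, fits the model on
#' the training datasets (hierarchically, so one pass per fold covers all
#' candidates) and evaluates the total log-likelihood on the held-out
#' dataset. The selected C maximises the held-out log-likelihood summed
#' over folds (ties go to the smaller C); the final model is refit on all
#' datasets at the selected C. Optionally draws MCMC posterior samples at
#' the selected C for each fold's model, as needed for cross-fold
#' agreement.
#'
#' @param z a `zscore_table` with a `dataset_id` column.
#' @param candidates candidate subtype counts (default 1:4).
#' @param folds a [split_by_dataset()] spec (built from `z` if omitted).
#' @param mcmc_iterations MCMC iterations per fold at the selected C
#'   (0 to skip; default 0).
#' @param seed seed for fits and MCMC.
#' @param ... passed to [sustain()] (`n_starts`, `max_em`, ...).
#' @return An object of class `sustain_cv`: `heldout` matrix (folds x
#'   candidates) of held-out log-likelihoods, `selected` C, `model` (final
#'   refit), `fold_models` (at the selected C), `fold_mcmc` (if sampled),
#'   and `candidates`.
#' @export
cv_sustain <- function(z, candidates = 1:4, folds = NULL,
                       mcmc_iterations = 0, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(folds)) folds <- split_by_dataset(z)
  candidates <- sort(unique(as.integer(candidates)))
  kmax <- max(candidates)
  ids <- attr(folds, "ids")
  heldout <- matrix(NA_real_, length(folds), length(candidates),
                    dimnames = list(ids, paste0("C", candidates)))
  fold_models <- vector("list", length(folds))
  names(fold_models) <- ids
  for (fi in seq_along(folds)) {
    tr <- z[z$dataset_id %in% folds[[fi]]$train, , drop = FALSE]
    te <- z[z$dataset_id == folds[[fi]]$test, , drop = FALSE]
    attributes(tr)$features <- attr(z, "features")
    attributes(te)$features <- attr(z, "features")
    fit <- try(sustain(tr, k = kmax, keep_path = TRUE, ...), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("fit failed in fold ", ids[fi], ": ",
              attr(fit, "condition")$message, "; fold excluded")
      next
    }
    for (ci in seq_along(candidates)) {
      heldout[fi, ci] <- total_loglik(te, fit$path[[candidates[ci]]])
    }
    fold_models[[fi]] <- fit$path
  }
  if (all(is.na(heldout))) stop("every cross-validation fold failed")
  sums <- colSums(heldout, na.rm = TRUE)
  selected <- candidates[which.max(sums)]   # which.max ties -> smaller C
  final <- sustain(z, k = selected, ...)
  fold_models_sel <- lapply(fold_models, function(p)
    if (is.null(p)) NULL else p[[selected]])
  fold_mcmc <- NULL
  if (mcmc_iterations > 0) {
    fold_mcmc <- vector("list", length(folds))
    names(fold_mcmc) <- ids
    for (fi in seq_along(folds)) {
      if (is.null(fold_models_sel[[fi]])) next
      tr <- z[z$dataset_id %in% folds[[fi]]$train, , drop = FALSE]
      attributes(tr)$features <- attr(z, "features")
      fold_mcmc[[fi]] <- sustain_mcmc(fold_models_sel[[fi]], tr,
                                      iterations = mcmc_iterations)
    }
  }
  structure(list(
    heldout = heldout, candidates = candidates, selected = selected,
    model = final, fold_models = fold_models_sel, fold_mcmc = fold_mcmc
  ), class = "sustain_cv")
}

#' @export
print.sustain_cv <- function(x, ...) {
  cat("Subtype-count selection by leave-one-dataset-out CV\n")
  cat("  held-out log-likelihood (summed over ", nrow(x$heldout),
      " folds):\n", sep = "")
  s <- colSums(x$heldout, na.rm = TRUE)
  for (i in seq_along(s))
    cat(sprintf("    C = %d: %s%s\n", x$candidates[i], format(s[i]),
                if (x$candidates[i] == x$selected) "  <- selected" else ""))
  invisible(x)
}

#' Bhattacharyya coefficient of two discrete distributions
#'
#' `sum_i sqrt(p_i q_i)`; 0 for disjoint support, 1 for identical
#' distributions.
#'
#' @param p,q non-negative vectors on the same support, each summing to 1
#'   (tolerance 1e-9).
#' @return Coefficient in `[0, 1]`.
#' @export
bhattacharyya <- function(p, q) {
  if (length(p) != length(q)) stop("distributions differ in support size")
  if (any(p < 0) || any(q < 0)) stop("negative probabilities")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("inputs must each sum to 1")
  min(1, sum(sqrt(p * q)))
}

# mean-over-events Bhattacharyya agreement of two positional distributions
positional_agreement <- function(P1, P2) {
  mean(vapply(seq_len(nrow(P1)), function(e) bhattacharyya(P1[e, ], P2[e, ]),
              numeric(1)))
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1))
    for (i in seq_len(n))
      out[[length(out) + 1]] <- append(p, n, after = i - 1L)
  out
}

#' Cross-fold agreement of sequence posteriors
#'
#' For each pair of folds, aligns subtypes by the bijection maximising the
#' total agreement (exhaustive over the C! options), where agreement of a
#' subtype pair is the mean over events of the Bhattacharyya coefficient
#' between the events' positional distributions; reports the mean and SD
#' over fold pairs for each subtype (indexed by the lower-numbered fold's
#' labels).
#'
#' @param fold_samples list of `sustain_mcmc` objects, one per fold, all
#'   on the same event grid and subtype count.
#' @return An object of class `agreement_report`: data.frame with per-
#'   subtype `mean` and `sd` of agreement, plus attribute `pairs` holding
#'   the per-pair aligned agreements and alignment maps.
#' @export
cross_fold_agreement <- function(fold_samples) {
  fold_samples <- Filter(Negate(is.null), fold_samples)
  if (length(fold_samples) < 2) stop("need samples from at least 2 folds")
  C <- fold_samples[[1]]$k
  E <- fold_samples[[1]]$grid$E
  for (fs in fold_samples) {
    if (fs$k != C) stop("folds disagree on the number of subtypes")
    if (fs$grid$E != E ||
        !identical(fs$grid$features, fold_samples[[1]]$grid$features))
      stop("folds use different event grids")
  }
  pos <- lapply(fold_samples, function(fs)
    lapply(seq_len(C), function(c) positional_distribution(fs, c)))
  perms <- all_permutations(C)
  pair_rows <- list()
  acc <- matrix(NA_real_, 0, C)
  for (a in seq_len(length(fold_samples) - 1)) {
    for (b in seq(a + 1, length(fold_samples))) {
      agree_mat <- outer(seq_len(C), seq_len(C),
                         Vectorize(function(i, j)
                           positional_agreement(pos[[a]][[i]], pos[[b]][[j]])))
      scores <- vapply(perms, function(pm)
        sum(agree_mat[cbind(seq_len(C), pm)]), numeric(1))
      best <- perms[[which.max(scores)]]
      aligned <- agree_mat[cbind(seq_len(C), best)]
      acc <- rbind(acc, aligned)
      pair_rows[[length(pair_rows) + 1]] <-
        list(fold_a = a, fold_b = b, map = best, agreement = aligned)
    }
  }
  out <- data.frame(subtype = seq_len(C),
                    mean = colMeans(acc),
                    sd = apply(acc, 2, stats::sd))
  structure(out, pairs = pair_rows, class = c("agreement_report",
                                              "data.frame"))
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Cross-fold sequence agreement (Bhattacharyya, mean over events)\n")
  NextMethod()
}
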