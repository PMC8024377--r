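# Fitting the z-score event-sequence mixture model (SuStaIn).

grid_args <- function(grid) {
  list(evFeat = as.integer(grid$event_feature),
       evZ = as.numeric(grid$event_z),
       zmax = as.numeric(grid$z_max))
}

visit_logmean <- function(Z, sequence, grid, sigma) {
  a <- grid_args(grid)
  as.numeric(cpp_visit_logmean(Z, as.integer(sequence), a$evFeat, a$evZ,
                               a$zmax, rep_len(sigma, ncol(Z))))
}

# uniform-ish random valid start: random positions, then each feature's
# events re-ordered among their own positions by ascending threshold
random_sequence <- function(grid) {
  s <- sample.int(grid$E)
  pos <- match(seq_len(grid$E), s)
  for (i in seq_along(grid$features)) {
    ev <- which(grid$event_feature == i)
    p <- sort(pos[ev])
    pos[ev] <- p
  }
  order(pos)
}

#' Total log-likelihood of a fitted model
#'
#' Sum over visits of the log mixture likelihood
#' `log sum_c f_c (1/(E+1)) sum_k L_c(k)` with a uniform stage prior.
#'
#' @param z a `zscore_table` or numeric matrix of z-scores (columns must
#'   match the model's grid features).
#' @param model a `sustain` object (or a list with `sequences`, `f`,
#'   `grid`, `sigma`).
#' @return Scalar log-likelihood.
#' @export
total_loglik <- function(z, model) {
  Z <- zscore_matrix(z, model$grid$features)
  if (nrow(Z) == 0) stop("empty z-score table")
  logm <- vapply(model$sequences, function(s)
    visit_logmean(Z, s, model$grid, model$sigma), numeric(nrow(Z)))
  logm <- matrix(logm, nrow = nrow(Z))
  lp <- sweep(logm, 2, log(model$f), `+`)
  mx <- apply(lp, 1, max)
  sum(mx + log(rowSums(exp(lp - mx))))
}

#' Maximum-likelihood event sequence for a single subtype
#'
#' Coordinate ascent from random valid starts: each event is removed and
#' reinserted at its best admissible position (the within-feature
#' threshold order z=1 < z=2 < z=3 is a hard constraint) until no move
#' improves the (optionally weighted) log-likelihood; the best sequence
#' over starts is returned.
#'
#' @param z z-score table or matrix.
#' @param grid an [event_grid()] over the columns of `z`.
#' @param starts number of random starts (>= 1).
#' @param sigma per-feature emission SD (default 1).
#' @param weights optional per-visit weights (EM responsibilities).
#' @param max_sweeps cap on full passes over events per start.
#' @param init optional starting sequence used for the first start.
#' @return List with `sequence` and `objective` (weighted log-likelihood).
#' @export
optimize_sequence <- function(z, grid, starts = 10, sigma = 1,
                              weights = NULL, max_sweeps = 50, init = NULL) {
  Z <- zscore_matrix(z, grid$features)
  if (starts < 1) stop("starts must be >= 1")
  sigma <- rep_len(sigma, ncol(Z))
  if (is.null(weights)) weights <- rep(1, nrow(Z))
  # visits with negligible responsibility contribute nothing measurable to
  # the weighted objective; dropping them keeps M-steps near cluster size
  keep <- weights > 1e-10 * max(weights)
  if (!all(keep)) {
    Z <- Z[keep, , drop = FALSE]
    weights <- weights[keep]
  }
  a <- grid_args(grid)
  best <- NULL
  for (s in seq_len(starts)) {
    s0 <- if (s == 1 && !is.null(init)) init else random_sequence(grid)
    fit <- cpp_optimize(Z, as.integer(s0), a$evFeat, a$evZ, a$zmax,
                        sigma, weights, as.integer(max_sweeps))
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  check_sequence(best$sequence, grid)
  list(sequence = as.integer(best$sequence), objective = best$objective)
}

# observed z minus the expected trajectory at each visit's modal stage
stage_residuals <- function(Z, sequence, grid, sigma) {
  a <- grid_args(grid)
  G <- cpp_traj(as.integer(sequence), a$evFeat, a$evZ, a$zmax, ncol(Z))
  Gs <- G / sigma
  ll <- sweep(Z, 2, sigma, `/`) %*% Gs
  ll <- sweep(ll, 2, 0.5 * colSums(Gs^2), `-`)
  k_hat <- max.col(ll, ties.method = "first") - 1L
  Z - t(G[, k_hat + 1, drop = FALSE])
}

# one EM run from given sequences/fractions; returns fitted pieces + trace
em_fit <- function(Z, grid, sigma, seqs, f, tol, max_em, max_sweeps = 2) {
  C <- length(seqs)
  logm <- vapply(seqs, function(s) visit_logmean(Z, s, grid, sigma),
                 numeric(nrow(Z)))
  logm <- matrix(logm, nrow = nrow(Z))
  trace <- numeric(0)
  conv <- FALSE
  for (it in seq_len(max_em)) {
    lp <- sweep(logm, 2, log(f), `+`)
    mx <- apply(lp, 1, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    trace <- c(trace, sum(lse))
    if (it > 1 && trace[it] - trace[it - 1] < tol) { conv <- TRUE; break }
    r <- exp(lp - lse)
    f <- pmax(colMeans(r), 1e-12)
    f <- f / sum(f)
    for (c in seq_len(C)) {
      opt <- optimize_sequence(Z, grid, starts = 1, sigma = sigma,
                               weights = r[, c], max_sweeps = max_sweeps,
                               init = seqs[[c]])
      seqs[[c]] <- opt$sequence
      logm[, c] <- visit_logmean(Z, seqs[[c]], grid, sigma)
    }
  }
  lp <- sweep(logm, 2, log(f), `+`)
  mx <- apply(lp, 1, max)
  lse <- mx + log(rowSums(exp(lp - mx)))
  r <- exp(lp - lse)
  list(sequences = seqs, f = f, loglik = sum(lse), responsibilities = r,
       trace = trace, converged = conv, iterations = length(trace))
}

#' Fit the subtype-and-stage event-sequence mixture model
#'
#' Fits a mixture of C event sequences to control-referenced z-scores.
#' Each subtype c is a strict ordering S_c of biomarker threshold events;
#' a visit at stage k of subtype c is modelled as Gaussian noise around
#' the piecewise-linear expected trajectory g(k | S_c), with the stage
#' marginalised under a uniform prior over 0..E.
#'
#' Fitting is hierarchical: the single-subtype model is estimated by
#' multi-start coordinate ascent; each larger model is initialised by
#' splitting, in turn, every cluster of the (C-1)-subtype solution into
#' two (2-means bisection on residuals from the parent trajectory, each
#' half refit) and keeping the best-scoring split, then refined by
#' expectation-maximisation, which alternates soft responsibility
#' assignment with re-optimisation of each sequence on responsibility-
#' weighted data until the log-likelihood gain falls below `tol`.
#'
#' @param x a `zscore_table` (from [compute_zscores()]) or numeric matrix
#'   with one column per selected feature.
#' @param k number of subtypes (>= 1).
#' @param thresholds z-score event thresholds (default 1, 2, 3).
#' @param z_max asymptotic z level after the last event (default 5).
#' @param sigma emission SD per feature; 1 by default since the data are
#'   control-referenced z-scores.
#' @param n_starts random starts for sequence optimisation (default 10).
#' @param max_em maximum EM iterations per candidate (default 100).
#' @param tol EM convergence tolerance in log-likelihood units.
#' @param max_sweeps optimizer sweep cap for cold (random-start) fits.
#' @param em_sweeps optimizer sweep cap inside EM M-steps; warm restarts
#'   rarely need more than a couple of passes (default 2).
#' @param split_em EM iterations used to score each candidate cluster
#'   split before the best split is refined with the full budget
#'   (default 2).
#' @param seed optional seed for the random starts and splits.
#' @param keep_path keep the fitted models for 1..k-1 subtypes in `$path`.
#' @param verbose print progress.
#' @return An object of class `sustain` with elements `grid`, `sequences`
#'   (list of k permutations), `f` (mixture fractions), `sigma`, `logLik`,
#'   `responsibilities`, `em_trace`, `converged`, `n`, and optionally
#'   `path`.
#' @seealso [predict.sustain()], [sustain_mcmc()], [cv_sustain()]
#' @examples
#' \donttest{
#' fx <- default_fixture()
#' nm <- fit_normative(fx$controls)
#' zs <- compute_zscores(fx$patients, nm, features = fx$config$affected)
#' fit <- sustain(zs, k = 1, n_starts = 2, seed = 1)
#' print(fit)
#' }
#' @export
sustain <- function(x, k = 1, thresholds = c(1, 2, 3), z_max = 5, sigma = 1,
                    n_starts = 10, max_em = 100, tol = 1e-4, max_sweeps = 50,
                    em_sweeps = 2, split_em = 2, seed = NULL,
                    keep_path = FALSE, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  Z <- zscore_matrix(x)
  if (is.null(colnames(Z))) stop("z-score columns must be named")
  if (k < 1) stop("k must be >= 1")
  if (nrow(Z) < 10 * k) stop("need at least 10 visits per subtype")
  grid <- event_grid(colnames(Z), thresholds, z_max)
  sigma <- rep_len(sigma, ncol(Z))

  # C = 1: multi-start ascent
  opt <- optimize_sequence(Z, grid, starts = n_starts, sigma = sigma,
                           max_sweeps = max_sweeps)
  fit <- list(sequences = list(opt$sequence), f = 1,
              loglik = opt$objective,
              responsibilities = matrix(1, nrow(Z), 1),
              trace = opt$objective, converged = TRUE, iterations = 1L)
  path <- list()
  if (keep_path || k == 1) path[[1]] <- fit

  C <- 1
  while (C < k) {
    C <- C + 1
    modal <- max.col(fit$responsibilities, ties.method = "first")
    cand_best <- NULL
    for (split_c in seq_len(C - 1)) {
      members <- which(modal == split_c)
      if (length(members) < 4) next
      # bisect the cluster on residuals from the parent trajectory at each
      # visit's modal stage: raw z-scores mostly encode severity (stage),
      # whereas the residual pattern encodes the *ordering* deviation that
      # distinguishes a latent subtype; a random bisection leaves two
      # near-identical halves whose symmetric EM start mixes poorly
      R <- stage_residuals(Z[members, , drop = FALSE],
                           fit$sequences[[split_c]], grid, sigma)
      km <- tryCatch(stats::kmeans(R, centers = 2, nstart = 2),
                     error = function(e) NULL)
      if (is.null(km) || min(km$size) < 2) {
        half <- sample(members, length(members) %/% 2)
      } else {
        half <- members[km$cluster == 1]
      }
      other <- setdiff(members, half)
      s_a <- optimize_sequence(Z[half, , drop = FALSE], grid, starts = 1,
                               sigma = sigma, max_sweeps = em_sweeps + 1,
                               init = fit$sequences[[split_c]])$sequence
      s_b <- optimize_sequence(Z[other, , drop = FALSE], grid, starts = 1,
                               sigma = sigma, max_sweeps = em_sweeps + 1,
                               init = fit$sequences[[split_c]])$sequence
      seqs <- append(fit$sequences[-split_c], list(s_a, s_b))
      f0 <- c(fit$f[-split_c], rep(fit$f[split_c] / 2, 2))
      # score the split with a short EM; only the winner gets refined
      cand <- em_fit(Z, grid, sigma, seqs, f0 / sum(f0), tol,
                     max_em = split_em, max_sweeps = em_sweeps)
      if (verbose)
        message("C=", C, " split cluster ", split_c, ": logLik ",
                format(cand$loglik))
      if (is.null(cand_best) || cand$loglik > cand_best$loglik)
        cand_best <- cand
    }
    if (is.null(cand_best))
      stop("no cluster large enough to split at C = ", C)
    fit <- em_fit(Z, grid, sigma, cand_best$sequences, cand_best$f, tol,
                  max_em = max_em, max_sweeps = em_sweeps)
    if (keep_path || C == k) {
      # polish: extra EM passes with a generous sweep budget tighten the
      # sequences once the partition has stabilised
      fit <- em_fit(Z, grid, sigma, fit$sequences, fit$f, tol,
                    max_em = if (C == k) 4L else 2L,
                    max_sweeps = max(em_sweeps, 8))
      path[[C]] <- fit
    }
    if (!fit$converged && C == k)
      warning("EM did not converge at C = ", C,
              "; returning best solution found")
  }

  out <- structure(list(
    grid = grid, sequences = fit$sequences, f = fit$f,
    sigma = stats::setNames(sigma, grid$features),
    logLik = fit$loglik, responsibilities = fit$responsibilities,
    em_trace = fit$trace, converged = fit$converged,
    k = k, n = nrow(Z)
  ), class = "sustain")
  if (keep_path) {
    out$path <- lapply(seq_along(path), function(ck) {
      p <- path[[ck]]
      structure(list(grid = grid, sequences = p$sequences, f = p$f,
                     sigma = out$sigma, logLik = p$loglik,
                     responsibilities = p$responsibilities,
                     em_trace = p$trace, converged = p$converged,
                     k = ck, n = nrow(Z)), class = "sustain")
    })
  }
  out
}

#' @export
print.sustain <- function(x, ...) {
  cat("Subtype-and-stage event sequence model\n")
  cat("  ", x$k, " subtype(s) over ", x$grid$E, " events (",
      length(x$grid$features), " features x {",
      paste(x$grid$thresholds, collapse = ","), "})\n", sep = "")
  cat("  mixture fractions: ", paste(format(round(x$f, 3)), collapse = " / "),
      "\n", sep = "")
  cat("  log-likelihood: ", format(x$logLik), " on ", x$n, " visits\n",
      sep = "")
  invisible(x)
}

#' @export
summary.sustain <- function(object, n_events = 5, ...) {
  lab <- event_labels(object$grid)
  cat("Subtype-and-stage event sequence model (", object$k,
      " subtypes, E = ", object$grid$E, ")\n", sep = "")
  for (c in seq_len(object$k)) {
    first <- lab[object$sequences[[c]][seq_len(min(n_events, object$grid$E))]]
    cat(sprintf("  subtype %d (f = %.3f): %s, ...\n", c, object$f[c],
                paste(first, collapse = " -> ")))
  }
  invisible(object)
}

#' @export
coef.sustain <- function(object, ...) {
  list(sequences = object$sequences, fractions = object$f)
}

#' @export
logLik.sustain <- function(object, ...) {
  structure(object$logLik, df = object$k - 1, nobs = object$n,
            class = "logLik")
}

#' Stage and subtype assignment for visits
#'
#' Posterior subtype membership `P(c | x)` proportional to
#' `f_c sum_k L_c(k)`, the modal subtype (ties to the lowest index), and
#' the stage posterior conditional on the modal subtype. Stage 0 means no
#' events have occurred; patients along a trajectory occupy stages 1..E.
#'
#' @param object a fitted `sustain` model.
#' @param newdata a `zscore_table` or z matrix over the model's features.
#' @param ... unused.
#' @return A data.frame carrying any key columns of `newdata` plus
#'   `p_subtype<c>` columns, `subtype`, `p_max`, `stage_mode` and
#'   `stage_mean`.
#' @export
predict.sustain <- function(object, newdata, ...) {
  Z <- zscore_matrix(newdata, object$grid$features)
  C <- object$k
  E <- object$grid$E
  a <- grid_args(object$grid)
  logm <- vapply(object$sequences, function(s)
    visit_logmean(Z, s, object$grid, object$sigma), numeric(nrow(Z)))
  logm <- matrix(logm, nrow = nrow(Z))
  lp <- sweep(logm, 2, log(object$f), `+`)
  mx <- apply(lp, 1, max)
  post <- exp(lp - mx - log(rowSums(exp(lp - mx))))
  subtype <- max.col(post, ties.method = "first")

  stage_mode <- integer(nrow(Z))
  stage_mean <- numeric(nrow(Z))
  for (c in seq_len(C)) {
    idx <- which(subtype == c)
    if (!length(idx)) next
    G <- cpp_traj(as.integer(object$sequences[[c]]), a$evFeat, a$evZ,
                  a$zmax, ncol(Z))
    Gs <- G / object$sigma
    Zs <- sweep(Z[idx, , drop = FALSE], 2, object$sigma, `/`)
    ll <- Zs %*% Gs
    ll <- sweep(ll, 2, 0.5 * colSums(Gs^2), `-`)   # N x (E+1), const dropped
    w <- exp(ll - apply(ll, 1, max))
    w <- w / rowSums(w)
    stage_mode[idx] <- max.col(w, ties.method = "first") - 1L
    stage_mean[idx] <- as.numeric(w %*% (0:E))
  }
  keys <- if (is.data.frame(newdata))
    newdata[, intersect(c(cohort_key_cols, "true_subtype", "true_stage"),
                        names(newdata)), drop = FALSE]
  else NULL
  out <- data.frame(post)
  names(out) <- paste0("p_subtype", seq_len(C))
  out$subtype <- subtype
  out$p_max <- post[cbind(seq_len(nrow(post)), subtype)]
  out$stage_mode <- stage_mode
  out$stage_mean <- stage_mean
  if (!is.null(keys)) out <- cbind(keys, out)
  rownames(out) <- NULL
  out
}

#' Simulate z-scores from a fitted model
#'
#' Draws a subtype from the mixture fractions, a stage uniformly over
#' 0..E, and observed z-scores as Gaussian noise around the expected
#' trajectory.
#'
#' @param object a `sustain` model.
#' @param nsim number of visits to simulate.
#' @param seed optional seed.
#' @param ... unused.
#' @return A data.frame with `subtype`, `stage` and one column per feature.
#' @export
simulate.sustain <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  E <- object$grid$E
  subtype <- sample.int(object$k, nsim, replace = TRUE, prob = object$f)
  stage <- sample(0:E, nsim, replace = TRUE)
  Z <- matrix(NA_real_, nsim, length(object$grid$features),
              dimnames = list(NULL, object$grid$features))
  for (c in seq_len(object$k)) {
    idx <- which(subtype == c)
    if (!length(idx)) next
    G <- event_trajectory(object$grid, object$sequences[[c]])
    mu <- t(G[, stage[idx] + 1, drop = FALSE])
    Z[idx, ] <- mu + matrix(stats::rnorm(length(mu)), nrow(mu)) %*%
      diag(object$sigma, ncol(Z))
  }
  data.frame(subtype = subtype, stage = stage, Z, check.names = FALSE)
}

#' Plot expected subtype trajectories
#'
#' Expected z-score of every feature against stage, one panel per
#' subtype.
#'
#' @param x a `sustain` model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sustain <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, x$k), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (c in seq_len(x$k)) {
    G <- event_trajectory(x$grid, x$sequences[[c]])
    graphics::matplot(0:x$grid$E, t(G), type = "l", lty = 1,
                      xlab = "stage", ylab = "expected z",
                      main = sprintf("subtype %d (f = %.2f)", c, x$f[c]), ...)
  }
  invisible(x)
}

#' Residual z-scores under the modal assignment
#'
#' Observed z minus the expected trajectory value at each visit's modal
#' subtype and stage.
#'
#' @param object a `sustain` model.
#' @param newdata z-score table or matrix; defaults must be supplied since
#'   the model does not store its training data.
#' @param ... unused.
#' @return Matrix of residuals, one row per visit.
#' @export
residuals.sustain <- function(object, newdata, ...) {
  Z <- zscore_matrix(newdata, object$grid$features)
  asg <- predict(object, newdata)
  R <- Z
  for (c in seq_len(object$k)) {
    idx <- which(asg$subtype == c)
    if (!length(idx)) next
    G <- event_trajectory(object$grid, object$sequences[[c]])
    R[idx, ] <- Z[idx, , drop = FALSE] -
      t(G[, asg$stage_mode[idx] + 1, drop = FALSE])
  }
  R
}
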