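# Metropolis-Hastings sampling of the posterior over event sequences.

# admissible insertion slots (1-based, into the sequence with e removed)
# for event e given the within-feature threshold order
admissible_slots <- function(S, e, grid) {
  reduced <- S[S != e]
  lo <- 1L
  hi <- length(S)
  fe <- grid$event_feature[e]
  ze <- grid$event_z[e]
  for (q in seq_along(reduced)) {
    if (grid$event_feature[reduced[q]] != fe) next
    if (grid$event_z[reduced[q]] < ze) lo <- q + 1L
    else { hi <- q; break }
  }
  lo:hi
}

insert_at <- function(reduced, e, j) append(reduced, e, after = j - 1L)

#' Sample the sequence posterior by MCMC
#'
#' Metropolis-Hastings over the space of valid event sequences: each
#' iteration moves one uniformly chosen event of one uniformly chosen
#' subtype to a uniformly chosen admissible position (a symmetric
#' proposal), accepting with probability `min(1, exp(delta log-lik))`.
#' Mixture fractions are refreshed every iteration by responsibility
#' re-normalisation. The default run length follows the training
#' protocol of 100,000 iterations; reduced runs are appropriate for
#' desk-scale data.
#'
#' @param object a fitted [sustain()] model (the chain starts from its
#'   maximum-likelihood sequences).
#' @param z the z-score table or matrix the model was fit to.
#' @param iterations total MCMC iterations (default 1e5).
#' @param burn_in fraction of iterations discarded (default 0.1).
#' @param thin keep every `thin`-th post-burn-in state (default 10).
#' @param seed optional seed.
#' @return An object of class `sustain_mcmc`: integer array `sequences`
#'   of dimension (samples, subtypes, E), matrix `fractions`, the
#'   log-likelihood `trace`, the acceptance rate and the run settings.
#' @export
sustain_mcmc <- function(object, z, iterations = 1e5, burn_in = 0.1,
                         thin = 10, seed = NULL) {
  stopifnot(inherits(object, "sustain"))
  if (!is.null(seed)) set.seed(seed)
  iterations <- as.integer(iterations)
  if (iterations < 1) stop("iterations must be >= 1")
  n_burn <- floor(iterations * burn_in)
  if (n_burn >= iterations) stop("burn-in leaves no samples")
  keep_at <- seq(n_burn + thin, iterations, by = thin)
  if (!length(keep_at)) stop("thinning leaves no samples")

  Z <- zscore_matrix(z, object$grid$features)
  grid <- object$grid
  C <- object$k
  E <- grid$E
  seqs <- object$sequences
  f <- rep_len(object$f, C)
  logm <- vapply(seqs, function(s) visit_logmean(Z, s, grid, object$sigma),
                 numeric(nrow(Z)))
  logm <- matrix(logm, nrow = nrow(Z))
  mix_ll <- function(logm, f) {
    lp <- sweep(logm, 2, log(f), `+`)
    mx <- lp[, 1]
    if (C > 1) for (cc in 2:C) mx <- pmax(mx, lp[, cc])
    lse <- mx + log(rowSums(exp(lp - mx)))
    list(ll = sum(lse), lp = lp, lse = lse)
  }
  cur <- mix_ll(logm, f)

  samp_seq <- array(NA_integer_, c(length(keep_at), C, E))
  samp_f <- matrix(NA_real_, length(keep_at), C)
  trace <- numeric(iterations)
  n_acc <- 0L
  k_out <- 1L
  for (it in seq_len(iterations)) {
    c_i <- sample.int(C, 1)
    e <- sample.int(E, 1)
    slots <- admissible_slots(seqs[[c_i]], e, grid)
    j <- if (length(slots) == 1) slots else slots[sample.int(length(slots), 1)]
    cand <- insert_at(seqs[[c_i]][seqs[[c_i]] != e], e, j)
    if (identical(cand, seqs[[c_i]])) {
      n_acc <- n_acc + 1L                # delta = 0, always accepted
    } else {
      new_col <- visit_logmean(Z, cand, grid, object$sigma)
      logm_new <- logm
      logm_new[, c_i] <- new_col
      prop <- mix_ll(logm_new, f)
      if (log(stats::runif(1)) < prop$ll - cur$ll) {
        seqs[[c_i]] <- cand
        logm <- logm_new
        cur <- prop
        n_acc <- n_acc + 1L
      }
    }
    # responsibility re-normalisation of the mixture fractions
    f_new <- pmax(colMeans(exp(cur$lp - cur$lse)), 1e-12)
    f <- f_new / sum(f_new)
    cur <- mix_ll(logm, f)
    trace[it] <- cur$ll
    if (k_out <= length(keep_at) && it == keep_at[k_out]) {
      for (cc in seq_len(C)) samp_seq[k_out, cc, ] <- seqs[[cc]]
      samp_f[k_out, ] <- f
      k_out <- k_out + 1L
    }
  }
  structure(list(
    sequences = samp_seq, fractions = samp_f, trace = trace,
    accept_rate = n_acc / iterations, iterations = iterations,
    burn_in = burn_in, thin = thin, grid = grid, k = C,
    map_sequences = seqs, map_f = f
  ), class = "sustain_mcmc")
}

#' @export
print.sustain_mcmc <- function(x, ...) {
  cat("Sequence posterior samples: ", dim(x$sequences)[1], " draws (",
      x$iterations, " iterations, ", round(100 * x$burn_in),
      "% burn-in, thin ", x$thin, ")\n", sep = "")
  cat("  acceptance rate: ", format(round(x$accept_rate, 3)), "\n", sep = "")
  invisible(x)
}

#' Positional distribution of events for one subtype
#'
#' For each event, the fraction of posterior samples placing it at each
#' sequence position; the uncertainty display behind positional-variance
#' plots and the input to cross-fold agreement.
#'
#' @param samples a `sustain_mcmc` object.
#' @param subtype subtype index.
#' @return E x E matrix, rows = events (grid order, labelled), columns =
#'   positions 1..E; rows sum to 1.
#' @export
positional_distribution <- function(samples, subtype = 1) {
  stopifnot(inherits(samples, "sustain_mcmc"))
  n <- dim(samples$sequences)[1]
  if (is.na(n) || n < 1) stop("no posterior samples")
  E <- samples$grid$E
  P <- matrix(0, E, E, dimnames = list(event_labels(samples$grid), NULL))
  for (s in seq_len(n)) {
    sq <- samples$sequences[s, subtype, ]
    P[cbind(sq, seq_len(E))] <- P[cbind(sq, seq_len(E))] + 1
  }
  P / n
}

#' Plot the positional uncertainty of a subtype's sequence
#'
#' @param x a `sustain_mcmc` object.
#' @param subtype subtype index.
#' @param ... passed to [graphics::image()].
#' @export
plot.sustain_mcmc <- function(x, subtype = 1, ...) {
  P <- positional_distribution(x, subtype)
  ord <- order(apply(P, 1, function(p) sum(p * seq_along(p))))
  graphics::image(seq_len(ncol(P)), seq_len(nrow(P)), t(P[ord, ]),
                  xlab = "sequence position", ylab = "event",
                  main = sprintf("subtype %d positional distribution",
                                 subtype), ...)
  invisible(x)
}
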