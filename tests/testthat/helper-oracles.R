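# Independent oracles: naive implementations used only to verify the
# package's vectorised/compiled paths on tiny instances.

# expected trajectory by direct interpolation between control points
oracle_trajectory <- function(grid, sequence, feature_idx, stage) {
  pos <- match(seq_len(grid$E), sequence)
  ev <- which(grid$event_feature == feature_idx)
  xp <- c(0, sort(pos[ev]))
  yp <- c(0, grid$event_z[ev][order(pos[ev])])
  if (max(xp) < grid$E) {
    xp <- c(xp, grid$E)
    yp <- c(yp, grid$z_max[[feature_idx]])
  }
  vapply(stage, function(k) {
    seg <- max(which(xp <= k))
    if (seg == length(xp)) return(yp[seg])
    yp[seg] + (k - xp[seg]) * (yp[seg + 1] - yp[seg]) / (xp[seg + 1] - xp[seg])
  }, numeric(1))
}

# brute-force mixture log-likelihood: explicit loops over visits, subtypes
# and stages with dnorm products
oracle_total_loglik <- function(Z, sequences, fractions, grid, sigma = 1) {
  sigma <- rep_len(sigma, ncol(Z))
  E <- grid$E
  total <- 0
  for (v in seq_len(nrow(Z))) {
    like_v <- 0
    for (c in seq_along(sequences)) {
      s_sum <- 0
      for (k in 0:E) {
        p <- 1
        for (i in seq_len(ncol(Z))) {
          g <- oracle_trajectory(grid, sequences[[c]], i, k)
          p <- p * stats::dnorm(Z[v, i], g, sigma[i])
        }
        s_sum <- s_sum + p
      }
      like_v <- like_v + fractions[c] * s_sum / (E + 1)
    }
    total <- total + log(like_v)
  }
  unname(total)
}

# all valid sequences (within-feature threshold order) by filtering the
# full permutation set; only usable for small E
oracle_valid_sequences <- function(grid) {
  perms <- list(1L)
  for (e in 2:grid$E) {
    perms <- unlist(lapply(perms, function(p)
      lapply(seq_len(e), function(i) append(p, e, after = i - 1L))),
      recursive = FALSE)
  }
  ok <- vapply(perms, function(p) {
    pos <- match(seq_len(grid$E), p)
    for (i in seq_along(grid$features)) {
      pf <- pos[grid$event_feature == i]
      if (any(diff(pf) <= 0)) return(FALSE)
    }
    TRUE
  }, logical(1))
  perms[ok]
}

# best label alignment of estimated vs true subtypes (exhaustive, C <= 4)
align_subtypes <- function(estimated, truth, C) {
  perms <- sustainMS:::all_permutations(C)
  tab <- table(factor(estimated, levels = 1:C), factor(truth, levels = 1:C))
  scores <- vapply(perms, function(p) sum(tab[cbind(p, 1:C)]), numeric(1))
  best <- perms[[which.max(scores)]]
  list(map = best, accuracy = max(scores) / length(truth))
}

kendall_tau_sequences <- function(s1, s2) {
  stats::cor(match(seq_along(s1), s1), match(seq_along(s2), s2),
             method = "kendall")
}
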