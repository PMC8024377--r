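#' Build the z-score event grid
#'
#' An event is a feature crossing a z-score threshold. With the default
#' thresholds 1, 2 and 3 (mild, moderate, severe abnormality in control
#' SD units) a model over 13 features has E = 39 events, hence stages
#' 0..39 where stage k means the first k events of a subtype's sequence
#' have occurred.
#'
#' Events are ordered feature-major: all thresholds of the first feature
#' (ascending), then the second, and so on.
#'
#' @param features character vector of feature names (no duplicates).
#' @param thresholds strictly increasing positive z thresholds, shared by
#'   all features.
#' @param z_max asymptotic z level approached after a feature's last
#'   event; must be >= the top threshold. Scalar or per-feature.
#' @return An object of class `event_grid`: list with `features`,
#'   `thresholds`, `E`, `event_feature` (index into `features`),
#'   `event_z` (threshold value per event) and `z_max` (per feature).
#' @examples
#' g <- event_grid(paste0("f", 1:13))
#' g$E  # 39
#' @export
event_grid <- function(features, thresholds = c(1, 2, 3), z_max = 5) {
  if (length(features) < 1) stop("need at least one feature")
  if (anyDuplicated(features)) stop("duplicate feature names")
  if (any(thresholds <= 0) || any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing and positive")
  F_n <- length(features)
  z_max <- rep_len(z_max, F_n)
  if (any(z_max < max(thresholds)))
    stop("z_max must be >= the largest threshold")
  structure(list(
    features = features,
    thresholds = thresholds,
    E = F_n * length(thresholds),
    event_feature = rep(seq_len(F_n), each = length(thresholds)),
    event_z = rep(thresholds, times = F_n),
    z_max = stats::setNames(z_max, features)
  ), class = "event_grid")
}

#' @export
print.event_grid <- function(x, ...) {
  cat("Event grid: ", length(x$features), " features x {",
      paste(x$thresholds, collapse = ", "), "} thresholds = ",
      x$E, " events\n", sep = "")
  invisible(x)
}

#' Event labels of a grid
#'
#' @param grid an [event_grid()].
#' @return Character vector `"<feature>:z>=<threshold>"`, one per event.
#' @export
event_labels <- function(grid) {
  paste0(grid$features[grid$event_feature], ":z>=", grid$event_z)
}

# validate that a sequence is a permutation of 1:E respecting the
# within-feature threshold order (z=1 before z=2 before z=3)
check_sequence <- function(s, grid) {
  if (length(s) != grid$E || !setequal(s, seq_len(grid$E)))
    stop("sequence must be a permutation of 1:", grid$E)
  pos <- match(seq_len(grid$E), s)   # position of each event
  for (i in seq_along(grid$features)) {
    p <- pos[grid$event_feature == i]
    if (any(diff(p) <= 0))
      stop("sequence violates threshold order for feature ",
           grid$features[i])
  }
  invisible(TRUE)
}

#' Expected biomarker trajectory along a sequence
#'
#' The expected z-score of each feature at each stage under a given event
#' sequence: piecewise-linear through (0, 0), then (p_r, z_r) for each of
#' the feature's threshold events at its (1-based) sequence position p_r,
#' and finally (E, z_max) -- dropped when the feature's last event already
#' sits at position E. Values are non-decreasing in stage.
#'
#' @param grid an [event_grid()].
#' @param sequence integer permutation of `1:E` (event ids in order of
#'   occurrence).
#' @param stages stages at which to evaluate (default `0:E`).
#' @return Matrix `length(features) x length(stages)` of expected
#'   z-scores, rows named by feature.
#' @examples
#' g <- event_grid("f1", thresholds = 1, z_max = 1)
#' event_trajectory(g, 1)          # 0 at stage 0, 1 at stage 1
#' @export
event_trajectory <- function(grid, sequence, stages = 0:grid$E) {
  check_sequence(sequence, grid)
  if (any(stages < 0 | stages > grid$E)) stop("stage out of range 0..", grid$E)
  pos <- match(seq_len(grid$E), sequence)
  G <- matrix(0, length(grid$features), length(stages),
              dimnames = list(grid$features, stages))
  for (i in seq_along(grid$features)) {
    ev <- which(grid$event_feature == i)
    xp <- c(0, pos[ev])
    yp <- c(0, grid$event_z[ev])
    if (xp[length(xp)] < grid$E) {
      xp <- c(xp, grid$E)
      yp <- c(yp, grid$z_max[[i]])
    }
    G[i, ] <- stats::approx(xp, yp, xout = stages, method = "linear",
                            rule = 2, ties = "ordered")$y
  }
  G
}

#' Stage likelihoods of one visit under one sequence
#'
#' Gaussian emission around the expected trajectory: the likelihood of a
#' visit's z-score vector at stage k is the product over features of
#' Normal(z_i; g_i(k | S), sigma_i), evaluated in log-space for stages
#' k = 0..E.
#'
#' @param z named numeric vector of z-scores covering all grid features.
#' @param sequence event sequence (permutation of `1:E`).
#' @param grid an [event_grid()].
#' @param sigma per-feature emission SD (default 1, the natural scale of
#'   control-referenced z-scores).
#' @param log return log-likelihoods (default FALSE).
#' @return Numeric vector of length E + 1 (stages 0..E).
#' @export
stage_likelihoods <- function(z, sequence, grid, sigma = 1, log = FALSE) {
  z <- z[grid$features]
  if (any(!is.finite(z))) stop("non-finite z-scores")
  sigma <- rep_len(sigma, length(grid$features))
  G <- event_trajectory(grid, sequence)
  ll <- colSums(stats::dnorm(z, mean = G, sd = sigma, log = TRUE))
  names(ll) <- colnames(G)
  if (log) ll else exp(ll)
}
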