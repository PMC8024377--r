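test_that("event grids have the product structure", {
  expect_equal(event_grid(paste0("f", 1:13))$E, 39)
  expect_equal(event_grid("only", thresholds = 1, z_max = 1)$E, 1)
  expect_equal(event_grid(paste0("f", 1:8))$E, 24)
  expect_error(event_grid(c("a", "a")), "duplicate")
  expect_error(event_grid("a", thresholds = c(2, 1)), "increasing")
  expect_error(event_grid("a", thresholds = c(1, 2, 3), z_max = 2), "z_max")
})

test_that("expected trajectories interpolate the control points", {
  g <- event_grid(paste0("f", 1:13))
  # a feature whose three events open the sequence
  s <- c(1:3, sequence_rest <- setdiff(1:39, 1:3))
  expect_equal(event_trajectory(g, s, stages = 0)[1, 1], 0)
  expect_equal(event_trajectory(g, s, stages = 2)[1, 1], 2)
  # beyond its last event the feature climbs linearly towards z_max = 5
  expect_equal(event_trajectory(g, s, stages = 21)[1, 1],
               3 + (21 - 3) * (5 - 3) / (39 - 3))
  expect_error(event_trajectory(g, s, stages = 40), "out of range")
  # compiled and reference implementations agree everywhere
  set.seed(2)
  for (rep in 1:5) {
    sq <- sustainMS:::random_sequence(g)
    G_cpp <- sustainMS:::cpp_traj(as.integer(sq),
                                  as.integer(g$event_feature),
                                  as.numeric(g$event_z),
                                  as.numeric(g$z_max), 13L)
    for (i in c(1, 7, 13))
      expect_equal(G_cpp[i, ], oracle_trajectory(g, sq, i, 0:39),
                   tolerance = 1e-12)
    expect_equal(unname(event_trajectory(g, sq)), unname(G_cpp),
                 tolerance = 1e-12)
  }
})

test_that("trajectories are non-decreasing in stage for every feature", {
  g <- event_grid(paste0("f", 1:6))
  set.seed(3)
  for (rep in 1:10) {
    G <- event_trajectory(g, sustainMS:::random_sequence(g))
    expect_true(all(diff(t(G)) >= -1e-12))
  }
})

test_that("stage likelihoods match the standard-normal hand case", {
  g <- event_grid("b", thresholds = 1, z_max = 1)
  L <- stage_likelihoods(c(b = 0), 1, g)
  expect_equal(unname(L["0"]), stats::dnorm(0), tolerance = 1e-9)
  expect_equal(unname(L["1"]), stats::dnorm(1), tolerance = 1e-9)
  expect_equal(unname(L["0"]), 0.39894, tolerance = 1e-4)
  expect_equal(unname(L["1"]), 0.24197, tolerance = 1e-4)
  expect_error(stage_likelihoods(c(b = NaN), 1, g), "non-finite")
})

test_that("a visit on the trajectory is staged at its true stage", {
  g <- event_grid(paste0("f", 1:5))
  set.seed(4)
  sq <- sustainMS:::random_sequence(g)
  G <- event_trajectory(g, sq)
  for (k_true in c(0, 4, 9, 15)) {
    z <- stats::setNames(G[, k_true + 1], g$features)
    L <- stage_likelihoods(z, sq, g, sigma = 0.05, log = TRUE)
    expect_equal(as.integer(names(which.max(L))), k_true)
    expect_true(all(is.finite(L)))
  }
})

test_that("total_loglik equals brute-force enumeration on small instances", {
  set.seed(5)
  for (rep in 1:3) {
    g <- event_grid(c("u", "v"), thresholds = c(1, 2), z_max = 3)
    seqs <- list(sustainMS:::random_sequence(g),
                 sustainMS:::random_sequence(g))
    f <- c(0.6, 0.4)
    Z <- matrix(stats::rnorm(10 * 2, 1), 10, 2,
                dimnames = list(NULL, g$features))
    model <- list(sequences = seqs, f = f, grid = g, sigma = c(1, 1))
    expect_equal(total_loglik(Z, model),
                 oracle_total_loglik(Z, seqs, f, g),
                 tolerance = 1e-8)
  }
})

test_that("duplicating the visits doubles the log-likelihood", {
  d <- small_data()
  g <- event_grid(d$cfg$affected)
  set.seed(6)
  model <- list(sequences = list(sustainMS:::random_sequence(g)), f = 1,
                grid = g, sigma = rep(1, 8))
  Z <- as.matrix(d$zs[1:50, d$cfg$affected])
  expect_equal(total_loglik(rbind(Z, Z), model),
               2 * total_loglik(Z, model), tolerance = 1e-8)
  expect_error(total_loglik(Z[0, , drop = FALSE], model), "empty")
})

test_that("sequence optimisation matches exhaustive search at E = 4", {
  g <- event_grid(c("u", "v"), thresholds = c(1, 2), z_max = 3)
  valid <- oracle_valid_sequences(g)
  expect_length(valid, 6)              # C(4,2) interleavings
  set.seed(7)
  for (rep in 1:3) {
    truth <- valid[[sample.int(6, 1)]]
    G <- event_trajectory(g, truth)
    stage <- sample(0:4, 60, replace = TRUE)
    Z <- t(G[, stage + 1]) + matrix(stats::rnorm(120, 0, 0.3), 60, 2)
    colnames(Z) <- g$features
    best_ll <- vapply(valid, function(s)
      total_loglik(Z, list(sequences = list(s), f = 1, grid = g,
                           sigma = c(1, 1))), numeric(1))
    opt <- optimize_sequence(Z, g, starts = 4)
    expect_equal(opt$sequence, valid[[which.max(best_ll)]])
    expect_equal(opt$objective, max(best_ll), tolerance = 1e-8)
  }
})

test_that("optimised sequences respect the threshold-order constraint", {
  d <- small_data()
  g <- event_grid(d$cfg$affected)
  Z <- as.matrix(d$zs[1:200, d$cfg$affected])
  set.seed(8)
  opt <- optimize_sequence(Z, g, starts = 2)
  expect_true(check_sequence(opt$sequence, g))
})

test_that("a planted single-subtype sequence is recovered exactly", {
  # near-noiseless visits covering every stage pin down the full ordering
  cfg <- small_config(seed = 99)
  g <- event_grid(cfg$affected)
  truth <- cfg$sequences[[1]]
  G <- event_trajectory(g, truth)
  set.seed(9)
  stage <- rep(0:g$E, each = 8)
  Z <- t(G[, stage + 1]) + matrix(stats::rnorm(length(stage) * 8, 0, 0.05),
                                  length(stage), 8)
  colnames(Z) <- g$features
  opt <- optimize_sequence(Z, g, starts = 3)
  expect_equal(kendall_tau_sequences(opt$sequence, truth), 1)
})
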