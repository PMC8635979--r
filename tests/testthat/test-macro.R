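test_that("PCCA+ recovers metastable blocks and degenerate cases", {
  # two 2-state blocks with weak coupling: crisp assignment = the blocks
  eps <- 1e-6
  Tb <- matrix(c(0.9 - eps, 0.1, eps, 0,
                 0.1, 0.9 - eps, 0, eps,
                 eps, 0, 0.9 - eps, 0.1,
                 0, eps, 0.1, 0.9 - eps), 4, 4, byrow = TRUE)
  m <- msm_from_matrix(Tb, lag = 1)
  mac <- pcca_macrostates(m, 2)
  expect_equal(mac$assignment[1], mac$assignment[2])
  expect_equal(mac$assignment[3], mac$assignment[4])
  expect_false(mac$assignment[1] == mac$assignment[3])
  expect_equal(rowSums(mac$chi), rep(1, 4), tolerance = 1e-8)
  expect_true(all(mac$chi >= -1e-12 & mac$chi <= 1 + 1e-12))

  # n_macro = 1: everything in one state with full membership
  mac1 <- pcca_macrostates(m, 1)
  expect_equal(as.numeric(mac1$chi), rep(1, 4))
  expect_equal(mac1$populations, 1)
})

test_that("PCCA+ grouping maximizes metastability on a three-state chain", {
  # states {1,2} exchange quickly with each other, slowly with 3
  Tm <- matrix(c(0.89, 0.1, 0.01,
                 0.1, 0.888, 0.012,
                 0.01, 0.012, 0.978), 3, 3, byrow = TRUE)
  m <- msm_from_matrix(Tm, lag = 1)
  mac <- pcca_macrostates(m, 2)
  # brute force over all 2-partitions: maximize trace of the coarse matrix
  parts <- list(list(c(1, 2), 3), list(c(1, 3), 2), list(c(2, 3), 1))
  meta <- vapply(parts, function(p) {
    tr <- 0
    for (s in p) {
      w <- m$pi[s] / sum(m$pi[s])
      tr <- tr + sum(w * rowSums(Tm[s, s, drop = FALSE]))
    }
    tr
  }, 0)
  best <- parts[[which.max(meta)]]
  # the exhaustive search singles out {1,2} vs {3}; PCCA+ must agree
  expect_equal(sort(best[[1]]), c(1, 2))
  expect_equal(mac$assignment[1], mac$assignment[2])
  expect_false(mac$assignment[1] == mac$assignment[3])
})

test_that("macrostate populations are stationary sums over members", {
  expect_equal(macro_populations(rep(0.25, 4), c(1, 1, 2, 2)), c(0.5, 0.5))
  expect_equal(macro_populations(c(0.7, 0.1, 0.1, 0.1), c(1, 2, 2, 2)),
               c(0.7, 0.3))
})

test_that("mean first-passage times solve the linear system", {
  # two-state closed form: MFPT = lag / T01, converted to microseconds
  m <- msm_from_matrix(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE),
                       lag = 20)
  expect_equal(mean_first_passage_time(m, 1, 2), 0.2, tolerance = 1e-12)

  expect_error(mean_first_passage_time(m, 1, 1), "disjoint")
  expect_error(mean_first_passage_time(m, integer(), 2), "nonempty")

  # three-state linear chain matches brute-force simulated passages
  T3 <- matrix(c(0.9, 0.1, 0,
                 0.05, 0.85, 0.1,
                 0, 0.1, 0.9), 3, 3, byrow = TRUE)
  m3 <- msm_from_matrix(T3, lag = 10)
  exact <- mean_first_passage_time(m3, 1, 3) * 1000  # ns
  sim <- oracle_simulated_mfpt(T3, 1, 3, lag = 10, n_events = 1e4, seed = 31)
  expect_equal(exact, sim, tolerance = 0.05)
})

test_that("MFPT shrinks as the connecting probability grows", {
  prev <- Inf
  for (p in c(0.01, 0.02, 0.05, 0.1, 0.2)) {
    Tm <- matrix(c(1 - p, p, 0,
                   0.1, 0.8, 0.1,
                   0, 0.1, 0.9), 3, 3, byrow = TRUE)
    m <- msm_from_matrix(Tm, lag = 1)
    cur <- mean_first_passage_time(m, 1, 3)
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("free-energy landscapes implement stationary reweighting", {
  # uniform weights and equal bin occupancy give a flat landscape at zero
  m <- msm_from_matrix(matrix(1, 1, 1), lag = 1)
  grid <- as.matrix(expand.grid(x = c(0.25, 0.75), y = c(0.25, 0.75)))
  P <- grid[rep(1:4, each = 25), ]
  m$dtrajs <- list(rep(1L, nrow(P)))
  fel <- free_energy_landscape(P, m, bins = 2, kT = 0.5962)
  expect_equal(max(abs(fel$dG)), 0, tolerance = 1e-12)
  expect_equal(sum(fel$density), 1, tolerance = 1e-12)

  # two bins with stationary weights 0.8/0.2: dG gap = kT ln 4
  m2 <- msm_from_matrix(matrix(c(0.9, 0.1, 0.4, 0.6), 2, 2, byrow = TRUE),
                        lag = 1, pi = c(0.8, 0.2))
  P2 <- cbind(c(rep(0, 50), rep(1, 50)), 0.5)
  m2$dtrajs <- list(c(rep(1L, 50), rep(2L, 50)))
  fel2 <- free_energy_landscape(P2, m2, bins = 2, kT = 0.5962)
  gap <- max(fel2$dG, na.rm = TRUE) - min(fel2$dG, na.rm = TRUE)
  expect_equal(gap, 0.5962 * log(4), tolerance = 1e-9)
  expect_equal(min(fel2$dG, na.rm = TRUE), 0)

  # empty bins are masked, never -kT log 0
  P3 <- cbind(c(rep(0, 10), rep(1, 10)), c(rep(0, 10), rep(1, 10)))
  m$dtrajs <- list(rep(1L, 20))
  fel3 <- free_energy_landscape(P3, m, bins = 2, kT = 0.5962)
  expect_true(anyNA(fel3$dG))
  expect_true(all(is.finite(fel3$dG[!is.na(fel3$dG)])))
})

test_that("barrier heights match the closed-form double-well profile", {
  set.seed(17)
  n <- 1e6
  w_open <- 0.2
  comp <- stats::runif(n) < w_open
  x <- ifelse(comp, rnorm(n, 2), rnorm(n, -2))
  m <- msm_from_matrix(matrix(1, 1, 1), lag = 1)
  m$dtrajs <- list(rep(1L, n))
  fel <- free_energy_landscape(cbind(x, rnorm(n)), m, bins = 80, kT = 0.5962)
  macro <- ifelse(x < 0, 1L, 2L)
  b <- barrier_height(fel, macro)
  # closed form: -kT log p(x) for the mixture, barrier from the deeper well
  dens <- function(z) 0.8 * stats::dnorm(z, -2) + 0.2 * stats::dnorm(z, 2)
  zz <- seq(-1.5, 1.5, length.out = 2001)
  g <- -0.5962 * log(dens(zz))
  g_min_source <- -0.5962 * log(dens(stats::optimize(function(z) -dens(z),
                                                     c(-3, -1))$minimum))
  expected <- max(g) - g_min_source
  expect_equal(b, expected, tolerance = 0.05)

  # scaling kT by 2 scales the barrier by 2
  fel2 <- free_energy_landscape(cbind(x, rnorm(n)), m, bins = 80,
                                kT = 2 * 0.5962)
  expect_equal(barrier_height(fel2, macro), 2 * b, tolerance = 1e-6)

  # single-well data cannot produce a barrier
  x1 <- rnorm(1e4)
  m$dtrajs <- list(rep(1L, 1e4))
  fel1 <- free_energy_landscape(cbind(x1, rnorm(1e4)), m, bins = 40,
                                kT = 0.5962)
  expect_error(barrier_height(fel1, rep(1L, 1e4)), "two macrostates")
})

test_that("hyperparameter scan finds a stable open-probability elbow", {
  kin <- default_kinetics()
  trajs <- lapply(1:10, function(i)
    emit_features(sample_markov_chain(kin, 2000, 1 + (i %% 4), seed = 400 + i),
                  kin, seed = 500 + i))
  model <- tica(trajs, lag = 20, kinetic_map = TRUE)
  proj <- lapply(trajs, function(x) predict(model, x, dims = 1:2))

  # single grid point: returned as-is
  single <- hyperparameter_scan(proj, cluster_grid = 10, lag_grid = 1)
  expect_equal(nrow(single$table), 1L)
  expect_equal(single$elbow_k, 10L)

  scan <- hyperparameter_scan(proj, cluster_grid = c(5, 10, 20, 30, 40),
                              lag_grid = 1, seed = 2, tol = 0.02)
  tab <- scan$table
  truth <- 0.5
  stable <- tab$p_open[tab$k >= 20]
  expect_true(all(abs(stable - truth) < 0.05))
  expect_lte(scan$elbow_k, 40L)
  # successive stable points vary less than the elbow tolerance
  expect_lt(max(abs(diff(stable))), 0.02)
})

test_that("open probability converges toward truth as data quadruple", {
  kin <- default_kinetics()
  p_open_for <- function(n_traj, seed0) {
    trajs <- lapply(seq_len(n_traj), function(i)
      emit_features(sample_markov_chain(kin, 2000, 1 + (i %% 4),
                                        seed = seed0 + i),
                    kin, seed = seed0 + 1000 + i))
    model <- tica(trajs, lag = 20, kinetic_map = TRUE)
    proj <- lapply(trajs, function(x) predict(model, x, dims = 1:2))
    cl <- cluster_microstates(proj, k = 20, seed = 3, nstart = 5)
    m <- markov_model(cl$dtrajs, lag = 20, stride_ns = 20)
    mac <- suppressWarnings(pcca_macrostates(m, 2))
    # both macrostates have truth 0.5; report the smaller for a signed error
    min(mac$populations)
  }
  # average the recovery error over replicates: convergence is a property
  # of the error distribution, not of one stochastic draw
  err5 <- mean(abs(vapply(c(600, 620, 640), function(s0)
    p_open_for(5, s0), 0) - 0.5))
  err20 <- mean(abs(vapply(c(700, 720, 740), function(s0)
    p_open_for(20, s0), 0) - 0.5))
  expect_lte(err20, err5 + 0.01)
  expect_lt(err20, 0.05)
})
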