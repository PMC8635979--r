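test_that("microstate clustering resolves separated clouds deterministically", {
  set.seed(1)
  X <- rbind(matrix(rnorm(400, mean = 0, sd = 0.05), ncol = 2),
             matrix(rnorm(400, mean = 5, sd = 0.05), ncol = 2))
  cl <- cluster_microstates(X, k = 2, seed = 3)
  centers <- cl$centers[order(cl$centers[, 1]), ]
  expect_equal(centers[1, ], colMeans(X[1:200, ]), tolerance = 0.01,
               ignore_attr = TRUE)
  expect_equal(centers[2, ], colMeans(X[201:400, ]), tolerance = 0.01,
               ignore_attr = TRUE)

  # re-assigning on the returned centers reproduces the labels
  expect_identical(assign_microstates(X, cl$centers), cl$dtrajs[[1]])

  # fitted inertia beats a random-center baseline
  set.seed(9)
  rand_centers <- X[sample(nrow(X), 2), ]
  lab <- assign_microstates(X, rand_centers)
  rand_inertia <- sum((X - rand_centers[lab, ])^2)
  expect_lte(cl$inertia, rand_inertia)

  expect_error(cluster_microstates(X[1:3, ], k = 10), "smaller")
})

test_that("transition counting follows the sliding-window definition", {
  cnt <- count_transitions(c(1L, 1L, 2L, 2L), lag = 1)
  expect_equal(cnt$C, matrix(c(1, 0, 1, 1), 2, 2), ignore_attr = TRUE)

  # two disconnected blocks: the larger one is the active set
  s <- c(rep(c(1L, 2L), 20), rep(3L, 5))
  s2 <- c(rep(3L, 5), rep(c(4L, 5L), 3))
  cnt2 <- count_transitions(list(s, s2), lag = 1)
  expect_equal(sort(cnt2$active), c(1L, 2L))

  # sliding and strided counting row-normalize to the same matrix within
  # sampling error on a long chain
  Tm <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  s <- sample_markov_chain(Tm, 1e4, 1, seed = 5)
  c_slide <- count_transitions(s, lag = 3, mode = "sliding")
  c_stride <- count_transitions(s, lag = 3, mode = "strided")
  T_slide <- c_slide$C / rowSums(c_slide$C)
  T_stride <- c_stride$C / rowSums(c_stride$C)
  expect_equal(T_slide, T_stride, tolerance = 0.05)
  expect_gt(sum(c_slide$C), sum(c_stride$C))  # sliding uses more pairs
})

test_that("reversible MLE reproduces closed-form two-state solutions", {
  # symmetric counts are already reversible
  e <- estimate_reversible(matrix(c(8, 2, 2, 8), 2, 2))
  expect_equal(e$T, matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(e$pi, c(0.5, 0.5), tolerance = 1e-8)

  # every two-state chain is reversible, so the MLE is row-normalized C
  e2 <- estimate_reversible(matrix(c(90, 10, 20, 80), 2, 2, byrow = TRUE))
  expect_equal(e2$T, matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(e2$pi, c(2 / 3, 1 / 3), tolerance = 1e-5)

  # detailed balance holds to machine precision
  pT <- e2$pi * e2$T
  expect_lt(max(abs(pT - t(pT))), 1e-12)
})

test_that("reversible MLE matches a generic constrained optimizer", {
  set.seed(2)
  for (r in 1:10) {
    C <- matrix(rpois(9, 25) + 1, 3, 3)
    e <- estimate_reversible(C)
    expect_lt(abs(e$loglik - oracle_reversible_loglik(C)), 1e-8)
    pT <- e$pi * e$T
    expect_lt(max(abs(pT - t(pT))), 1e-12)
    expect_equal(rowSums(e$T), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("markov_model spectra are real with correct stationary vector", {
  kin <- default_kinetics()
  dts <- lapply(1:16, function(i) sample_markov_chain(kin, 5000, 1 + (i %% 4),
                                                      seed = 40 + i))
  m <- markov_model(dts, lag = 20, stride_ns = 20)
  expect_equal(m$eigenvalues[1], 1, tolerance = 1e-10)
  expect_true(all(abs(m$eigenvalues) <= 1 + 1e-10))
  # pi is the leading left eigenvector
  expect_equal(as.numeric(m$pi %*% m$T), as.numeric(m$pi), tolerance = 1e-10)
  # microstate pi close to the uniform truth (basin occupancies mix on the
  # slow 2-us timescale, so sampling error is the dominant term)
  expect_lt(max(abs(as.numeric(m$pi) - 0.25)), 0.05)
})

test_that("implied timescales are flat for Markovian data and closed-form", {
  # closed form at a fixed lag
  m <- msm_from_matrix(matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2), lag = 20)
  t2 <- -20 / log(m$eigenvalues[2])
  expect_equal(t2, -20 / log(0.8), tolerance = 1e-12)

  Tm <- matrix(c(0.95, 0.05, 0.1, 0.9), 2, 2, byrow = TRUE)
  dts <- lapply(1:8, function(i) sample_markov_chain(Tm, 1e4, 1, seed = 60 + i))
  its <- implied_timescales(dts, lags = c(1, 2, 3, 5), stride_ns = 1,
                            n_timescales = 1, nboot = 20, seed = 3)
  truth <- -1 / log(1 - 0.05 - 0.1)
  # the true timescale lies in the bootstrap interval at every lag
  expect_true(all(its$lo_ns <= truth & truth <= its$hi_ns))
  # and the point estimates vary by less than 10% across lags
  expect_lt(diff(range(its$timescale_ns)) / mean(its$timescale_ns), 0.1)

  # permuting state labels leaves timescales unchanged
  perm <- c(2L, 1L)
  dts_perm <- lapply(dts, function(s) perm[s])
  its_perm <- implied_timescales(dts_perm, lags = c(1, 3), n_timescales = 1)
  its_base <- implied_timescales(dts, lags = c(1, 3), n_timescales = 1)
  expect_equal(its_perm$timescale_ns, its_base$timescale_ns,
               tolerance = 1e-10)
})

test_that("Chapman-Kolmogorov test accepts Markovian and rejects lumped data", {
  # self-consistency: data simulated from a true Markov chain agree
  T2 <- matrix(c(0.95, 0.05, 0.1, 0.9), 2, 2, byrow = TRUE)
  dts <- lapply(1:5, function(i) sample_markov_chain(T2, 2e4, 1, seed = i))
  ck <- ck_test(dts, lag = 1, macro_sets = list(A = 1, B = 2), k_steps = 1:5,
                nboot = 15, seed = 9)
  dev <- abs(ck$predicted - ck$estimated)
  sig <- sqrt(ck$se_predicted^2 + ck$se_estimated^2)
  expect_true(all(dev[ck$k > 1] <= 2 * sig[ck$k > 1]))
  expect_true(all(ck$ok))

  # a hidden three-state chain lumped to two symbols is detectably
  # non-Markovian at k = 5
  Th <- matrix(c(0.995, 0.005, 0,
                 0.005, 0.895, 0.1,
                 0, 0.1, 0.9), 3, 3, byrow = TRUE)
  dts_h <- lapply(1:20, function(i)
    c(1L, 1L, 2L)[sample_markov_chain(Th, 3e4, 1, seed = 100 + i)])
  ck_h <- ck_test(dts_h, lag = 1, macro_sets = list(A = 1, B = 2),
                  k_steps = c(1, 5), nboot = 20, seed = 4)
  aa <- ck_h[ck_h$from == "A" & ck_h$to == "A" & ck_h$k == 5, ]
  z <- abs(aa$predicted - aa$estimated) /
    sqrt(aa$se_predicted^2 + aa$se_estimated^2)
  expect_gt(z, 2)
})

test_that("estimation is invariant under cyclic relabeling of subunit blocks", {
  kin <- default_kinetics()
  trajs <- lapply(1:6, function(i)
    emit_features(sample_markov_chain(kin, 4000, 1 + (i %% 4), seed = 200 + i),
                  kin, seed = 300 + i))
  run_pi <- function(tr_list) {
    expanded <- do.call(c, lapply(tr_list, expand_feature_blocks))
    model <- tica(expanded, lag = 20, kinetic_map = TRUE)
    proj <- lapply(expanded, function(x) predict(model, x, dims = 1:2))
    cl <- cluster_microstates(proj, k = 12, seed = 5, nstart = 5)
    m <- markov_model(cl$dtrajs, lag = 20, stride_ns = 20)
    mac <- suppressWarnings(pcca_macrostates(m, 2))
    sort(mac$populations)
  }
  base <- run_pi(trajs)
  # cyclic relabeling of the input blocks = feeding rotated copies; the
  # pooled expanded estimate must be unchanged up to k-means determinism
  rotated <- lapply(trajs, function(x) expand_feature_blocks(x)[[2]])
  shifted <- run_pi(rotated)
  expect_lt(max(abs(base - shifted)), 0.005)
})
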