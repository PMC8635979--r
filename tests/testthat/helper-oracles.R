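# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: rotations are searched numerically instead of
# solved by SVD, likelihoods are maximized by a generic optimizer instead of
# the fixed-point iteration, and passage times are measured by simulation.

# brute-force optimal-superposition RMSD: numeric search over Euler angles
oracle_superpose_rmsd <- function(P, Q, restarts = 8) {
  P <- sweep(as.matrix(P), 2, colMeans(P))
  Q <- sweep(as.matrix(Q), 2, colMeans(Q))
  rotmat <- function(a) {
    Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
    Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
    Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) sqrt(mean(rowSums((Q - P %*% t(rotmat(a)))^2)))
  best <- Inf
  set.seed(99)
  starts <- rbind(c(0, 0, 0), matrix(stats::runif(3 * (restarts - 1), -pi, pi),
                                     ncol = 3))
  for (r in seq_len(nrow(starts))) {
    o <- stats::optim(starts[r, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# reversible-MLE log-likelihood via a generic box-free optimizer over the
# log of the symmetric flow parameters
oracle_reversible_loglik <- function(C) {
  k <- nrow(C)
  ut <- upper.tri(matrix(0, k, k), diag = TRUE)
  nll <- function(theta) {
    X <- matrix(0, k, k)
    X[ut] <- exp(theta)
    X[lower.tri(X)] <- t(X)[lower.tri(X)]
    T <- X / rowSums(X)
    -sum(C[C > 0] * log(T[C > 0]))
  }
  o <- stats::optim(rep(0, sum(ut)), nll, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  o <- stats::optim(o$par, nll, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  -o$value
}

# mean first-passage time by direct simulation of passage events
oracle_simulated_mfpt <- function(T, source_states, target_states, lag,
                                  n_events = 1e4, seed = 1) {
  pi <- pentagate::stationary_distribution(T)
  cum <- t(apply(T, 1, cumsum))
  set.seed(seed)
  w <- pi[source_states] / sum(pi[source_states])
  times <- numeric(n_events)
  for (e in seq_len(n_events)) {
    s <- sample(source_states, 1, prob = w)
    t_steps <- 0L
    while (!(s %in% target_states)) {
      s <- findInterval(stats::runif(1), cum[s, ]) + 1L
      t_steps <- t_steps + 1L
    }
    times[e] <- t_steps
  }
  mean(times) * lag
}

# stationary AR(1) series with unit marginal variance
ar1_series <- function(n, phi, seed = 1) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n - 1, sd = sqrt(1 - phi^2))
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t - 1]
  x
}

# regular-pentagon chord length between vertices `sep` steps apart
pentagon_chord <- function(radius, sep) 2 * radius * sin(pi * sep / 5)

# small deterministic pseudo-random coordinate jitter
jitter_structure <- function(s, sd = 0.5, seed = 1) {
  set.seed(seed)
  pentagate::`coords<-`(s, coords(s) + matrix(stats::rnorm(length(coords(s)),
                                                           sd = sd),
                                              nrow(coords(s)), 3))
}

# random rigid-body transform of a coarse structure
random_rigid_motion <- function(s, seed = 1) {
  set.seed(seed)
  a <- stats::runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
  shift <- stats::runif(3, -20, 20)
  pentagate::`coords<-`(s, sweep(coords(s) %*% t(Rz %*% Ry %*% Rx), 2, -shift))
}
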