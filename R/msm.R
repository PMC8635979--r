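# timescales -tau/log(lambda); NA for non-positive or unit eigenvalues
.its_from_lambda <- function(lam, lag) {
  out <- rep(NA_real_, length(lam))
  sel <- is.finite(lam) & lam > 0 & lam < 1
  out[sel] <- -lag / log(lam[sel])
  out
}

#' k-means microstate discretization of tICA projections
#'
#' k-means++-style best-of-restarts clustering (via [stats::kmeans()] with
#' multiple random starts, lowest within-cluster sum of squares kept),
#' followed by nearest-center assignment of every frame. Center fitting may
#' run on an evenly spaced subsample of the pooled frames (`fit_sample`) —
#' standard practice for large trajectory sets — while assignment always
#' covers every frame. Nearest-center ties break toward the lowest center
#' index, and the k-means seed is fixed and recorded, so discretization is
#' deterministic.
#'
#' @param projections projection matrix or list of per-trajectory matrices.
#' @param k number of microstates (default 300).
#' @param seed integer seed for the k-means restarts.
#' @param nstart number of random restarts.
#' @param iter.max k-means iteration cap.
#' @param fit_sample optional cap on the number of frames used to fit the
#'   centers.
#' @return list of class `microstates`: `centers`, `dtrajs` (list of
#'   integer vectors), `inertia` (total within-cluster sum of squares over
#'   all frames), `k`, `seed`.
#' @export
cluster_microstates <- function(projections, k = 300L, seed = 1L,
                                nstart = 10L, iter.max = 100L,
                                fit_sample = NULL) {
  plist <- if (is.list(projections)) lapply(projections, as.matrix)
           else list(as.matrix(projections))
  X <- do.call(rbind, plist)
  k <- as.integer(k)
  if (k >= nrow(X)) stop("k must be smaller than the number of frames")
  Xfit <- X
  if (!is.null(fit_sample) && nrow(X) > fit_sample)
    Xfit <- X[round(seq(1, nrow(X), length.out = fit_sample)), , drop = FALSE]
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  # near-duplicate projected frames make Hartigan-Wong emit spurious
  # Quick-TRANSfer convergence warnings; the restarts make these harmless
  km <- withCallingHandlers(
    stats::kmeans(Xfit, centers = k, nstart = nstart, iter.max = iter.max),
    warning = function(w) {
      if (grepl("Quick-TRANSfer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  centers <- km$centers
  dtrajs <- lapply(plist, assign_microstates, centers = centers)
  inertia <- 0
  off <- 0L
  for (i in seq_along(plist)) {
    d <- plist[[i]] - centers[dtrajs[[i]], , drop = FALSE]
    inertia <- inertia + sum(d * d)
  }
  structure(list(centers = centers, dtrajs = dtrajs, inertia = inertia,
                 k = k, seed = seed),
            class = "microstates")
}

#' Assign frames to their nearest microstate center
#'
#' @param X frames x dims matrix.
#' @param centers k x dims center matrix.
#' @param chunk frames per block (bounds memory on long trajectories).
#' @return integer vector of 1-based center indices (ties to the lowest
#'   index).
#' @export
assign_microstates <- function(X, centers, chunk = 100000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  out <- integer(n)
  c2 <- rowSums(centers^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    G <- X[s:e, , drop = FALSE] %*% t(centers)
    D <- sweep(-2 * G, 2, c2, `+`)
    out[s:e] <- max.col(-D, ties.method = "first")
  }
  out
}

#' @export
print.microstates <- function(x, ...) {
  cat("microstates:", x$k, "k-means centers,",
      sum(vapply(x$dtrajs, length, 0L)), "frames assigned\n")
  invisible(x)
}

#' Count microstate transitions at a lag
#'
#' Sliding-window counting (`C[i, j]` = number of observed pairs `i` at `t`,
#' `j` at `t + lag`; maximal data use) or strided counting over
#' non-overlapping windows. The active set is the largest strongly connected
#' component of the directed count graph; ties break toward the component
#' containing the lowest state index.
#'
#' @param dtrajs integer vector or list of discrete trajectories (1-based
#'   states).
#' @param lag lag in frames (>= 1).
#' @param n_states total number of states (default: maximum observed).
#' @param mode `"sliding"` or `"strided"`.
#' @return list with the full count matrix `C`, the `active` state indices,
#'   and the lag.
#' @export
count_transitions <- function(dtrajs, lag = 1L, n_states = NULL,
                              mode = c("sliding", "strided")) {
  mode <- match.arg(mode)
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  dtrajs <- lapply(dtrajs, as.integer)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be at least one frame")
  if (is.null(n_states)) n_states <- max(vapply(dtrajs, max, 0L))
  k <- as.integer(n_states)
  C <- matrix(0, k, k)
  for (s in dtrajs) {
    n <- length(s)
    if (n <= lag) next
    if (mode == "sliding") {
      i <- s[seq_len(n - lag)]
      j <- s[seq_len(n - lag) + lag]
    } else {
      idx <- seq(1L, n, by = lag)
      if (length(idx) < 2L) next
      i <- s[idx[-length(idx)]]
      j <- s[idx[-1L]]
    }
    C <- C + matrix(tabulate(i + (j - 1L) * k, nbins = k * k), k, k)
  }
  if (sum(C) == 0) stop("no transition pairs at this lag")
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  # keep only components that actually carry counts
  sizes <- vapply(seq_len(comp$no), function(cc) {
    m <- which(comp$membership == cc)
    sum(C[m, m, drop = FALSE])
  }, 0)
  best <- which(comp$csize == max(comp$csize[sizes > 0] , na.rm = TRUE) &
                sizes > 0)[1]
  active <- which(comp$membership == best)
  if (length(active) == 0L) stop("empty active set")
  list(C = C, active = active, lag = lag)
}

#' Reversible maximum-likelihood transition matrix
#'
#' Maximum-likelihood estimation of a row-stochastic transition matrix under
#' the detailed-balance constraint, by fixed-point iteration on the
#' unnormalized edge flows `x_ij`:
#' `x_ij <- (c_ij + c_ji) / (c_i / x_i + c_j / x_j)`,
#' iterated until the relative log-likelihood change falls below `tol`. The
#' stationary distribution is the normalized row sum of the converged flows,
#' and `pi_i T_ij = pi_j T_ji` holds to numerical precision by construction.
#'
#' @param C square count matrix, connected on its support.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap (error with the last residual if
#'   exceeded).
#' @return list with `T`, `pi`, `loglik`, `iterations`.
#' @export
estimate_reversible <- function(C, tol = 1e-13, max_iter = 1e6) {
  C <- as.matrix(C)
  k <- nrow(C)
  if (sum(C) == 0) stop("count matrix is empty")
  Csym <- C + t(C)
  X <- Csym / sum(Csym)
  ci <- rowSums(C)
  support <- C > 0
  ll <- function(T) sum(C[support] * log(T[support]))
  xi <- rowSums(X)
  T <- X / xi
  ll_old <- ll(T)
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- outer(ci / xi, ci / xi, `+`)
    Xn <- ifelse(Csym > 0, Csym / denom, 0)
    Xn <- (Xn + t(Xn)) / 2  # enforce exact symmetry against rounding
    Xn <- Xn / sum(Xn)
    X <- Xn
    xi <- rowSums(X)
    T <- X / xi
    ll_new <- ll(T)
    if (is.finite(ll_old) &&
        abs(ll_new - ll_old) <= tol * (abs(ll_old) + 1e-300)) break
    if (it >= max_iter)
      stop("reversible MLE did not converge; last log-likelihood residual ",
           signif(abs(ll_new - ll_old), 3))
    ll_old <- ll_new
  }
  pi <- xi / sum(xi)
  list(T = T, pi = pi, loglik = ll_new, iterations = it)
}

#' Fit a reversible Markov state model from discrete trajectories
#'
#' Sliding-window transition counting at the requested lag, restriction to
#' the largest strongly connected set, and reversible maximum-likelihood
#' estimation ([estimate_reversible()]). Frames outside the active set are
#' excluded from the stationary distribution (and later from landscapes);
#' their count is reported.
#'
#' @param dtrajs discrete trajectory (integer vector) or list of them.
#' @param lag MSM lag time in ns.
#' @param stride_ns physical time per frame (ns); `lag / stride_ns` must be
#'   a whole number of frames.
#' @param centers optional microstate centers to carry along (used by
#'   landscape and macrostate labeling helpers).
#' @param mode counting mode, see [count_transitions()].
#' @return an object of class `msm`: transition matrix `T` (active set),
#'   stationary distribution `pi`, real eigenvalue spectrum, count matrix,
#'   active state ids, discrete trajectories mapped to active indices (NA
#'   for excluded frames), lag bookkeeping.
#' @export
markov_model <- function(dtrajs, lag = 20, stride_ns = 1, centers = NULL,
                         mode = "sliding") {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  Lf <- lag / stride_ns
  if (abs(Lf - round(Lf)) > 1e-9)
    stop("lag must be a whole number of frames")
  Lf <- as.integer(round(Lf))
  cnt <- count_transitions(dtrajs, lag = Lf, mode = mode)
  act <- cnt$active
  Ca <- cnt$C[act, act, drop = FALSE]
  est <- estimate_reversible(Ca)
  spec <- .reversible_spectrum(est$T, est$pi)
  amap <- rep(NA_integer_, nrow(cnt$C))
  amap[act] <- seq_along(act)
  dtrajs_active <- lapply(dtrajs, function(s) amap[s])
  excluded <- sum(vapply(dtrajs_active, function(s) sum(is.na(s)), 0L))
  structure(list(T = est$T, pi = est$pi, eigenvalues = spec$values,
                 eigenvectors = spec$vectors, C = Ca, active = act,
                 dtrajs = dtrajs_active, n_states_total = nrow(cnt$C),
                 excluded_frames = excluded, lag = lag,
                 lag_frames = Lf, stride_ns = stride_ns,
                 centers = if (!is.null(centers)) centers[act, , drop = FALSE],
                 loglik = est$loglik),
            class = "msm")
}

# real spectrum and right eigenvectors of a reversible T via the symmetric
# similarity transform D^(1/2) T D^(-1/2)
.reversible_spectrum <- function(T, pi) {
  s <- sqrt(pi)
  S <- T * outer(s, 1 / s)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  psi <- e$vectors / s
  # normalize sign: largest-magnitude entry positive
  for (c in seq_len(ncol(psi))) {
    m <- which.max(abs(psi[, c]))
    if (psi[m, c] < 0) psi[, c] <- -psi[, c]
  }
  list(values = e$values, vectors = psi)
}

#' Build a Markov state model object from a known transition matrix
#'
#' Wraps an externally specified (typically analytic) reversible transition
#' matrix in the same object returned by [markov_model()], so closed-form
#' chains can be fed to [mean_first_passage_time()], [pcca_macrostates()]
#' and related analyses.
#'
#' @param T row-stochastic transition matrix.
#' @param lag lag time in ns.
#' @param pi stationary distribution (default: computed as the leading left
#'   eigenvector).
#' @return an object of class `msm`.
#' @export
msm_from_matrix <- function(T, lag = 20, pi = NULL) {
  T <- as.matrix(T)
  k <- nrow(T)
  if (any(abs(rowSums(T) - 1) > 1e-10))
    stop("transition matrix rows must sum to 1")
  if (is.null(pi)) pi <- stationary_distribution(T)
  db <- max(abs(pi * T - t(pi * T)))
  if (db > 1e-8)
    warning("transition matrix violates detailed balance (residual ",
            signif(db, 3), "); spectrum may be complex")
  spec <- .reversible_spectrum(T, pi)
  structure(list(T = T, pi = pi, eigenvalues = spec$values,
                 eigenvectors = spec$vectors, C = NULL,
                 active = seq_len(k), dtrajs = list(),
                 n_states_total = k, excluded_frames = 0L,
                 lag = lag, lag_frames = NA_integer_, stride_ns = NA_real_,
                 centers = NULL, loglik = NA_real_),
            class = "msm")
}

#' @export
print.msm <- function(x, ...) {
  cat("Reversible Markov state model\n")
  cat("  lag:", x$lag, "ns (", x$lag_frames, "frames );",
      length(x$active), "of", x$n_states_total, "microstates active\n")
  lam <- x$eigenvalues
  its <- .its_from_lambda(lam, x$lag)[-1]
  cat("  slowest implied timescales (ns):",
      paste(signif(utils::head(its, 3), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.msm <- function(object, ...) {
  lam <- object$eigenvalues
  its <- .its_from_lambda(lam, object$lag)
  list(lag_ns = object$lag, n_active = length(object$active),
       excluded_frames = object$excluded_frames,
       implied_timescales_ns = its[-1], stationary = object$pi,
       loglik = object$loglik)
}

#' Implied relaxation timescales across lag times
#'
#' Re-estimates a reversible MSM at each lag and reports
#' `t_i(tau) = -tau / log(lambda_i(tau))` in physical units. Flat curves in
#' `tau` indicate Markovian behavior at that lag. Non-positive eigenvalues
#' yield `NA` timescales.
#'
#' @param dtrajs discrete trajectories (vector or list).
#' @param lags lag times in frames.
#' @param stride_ns physical time per frame (ns).
#' @param n_timescales number of (non-stationary) timescales to report.
#' @param nboot optional number of trajectory bootstrap replicates for
#'   standard errors (0 = none).
#' @param seed bootstrap seed.
#' @return data frame with columns `lag_ns`, `process`, `timescale_ns` (and
#'   `se_ns`, `lo_ns`, `hi_ns` when `nboot > 0`).
#' @export
implied_timescales <- function(dtrajs, lags, stride_ns = 1,
                               n_timescales = 3L, nboot = 0L, seed = 1L) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  one <- function(dt, lagf) {
    m <- tryCatch(markov_model(dt, lag = lagf * stride_ns,
                               stride_ns = stride_ns),
                  error = function(e) NULL)
    if (is.null(m)) return(rep(NA_real_, n_timescales))
    lam <- m$eigenvalues[-1]
    out <- .its_from_lambda(lam, m$lag)
    out <- out[seq_len(min(n_timescales, length(out)))]
    c(out, rep(NA_real_, n_timescales - length(out)))
  }
  rows <- list()
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  for (lagf in lags) {
    ts <- one(dtrajs, lagf)
    if (nboot > 0) {
      B <- replicate(nboot, {
        idx <- sample.int(length(dtrajs), replace = TRUE)
        one(dtrajs[idx], lagf)
      })
      B <- matrix(B, nrow = n_timescales)
      se <- apply(B, 1, stats::sd, na.rm = TRUE)
      lo <- apply(B, 1, stats::quantile, probs = 0.025, na.rm = TRUE)
      hi <- apply(B, 1, stats::quantile, probs = 0.975, na.rm = TRUE)
      rows[[length(rows) + 1L]] <-
        data.frame(lag_ns = lagf * stride_ns, process = seq_len(n_timescales),
                   timescale_ns = ts, se_ns = se, lo_ns = lo, hi_ns = hi)
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(lag_ns = lagf * stride_ns, process = seq_len(n_timescales),
                   timescale_ns = ts)
    }
  }
  do.call(rbind, rows)
}

#' Chapman-Kolmogorov test on macrostate sets
#'
#' Compares set-to-set transition probabilities predicted by propagating the
#' base model, `T(tau)^k`, against probabilities re-estimated from the data
#' at lag `k * tau`. Source sets are weighted by the base model's stationary
#' distribution. Standard errors come from bootstrap resampling of whole
#' trajectories; lags at which re-estimation is impossible are flagged
#' rather than dropped.
#'
#' @param dtrajs discrete trajectories used to fit the model.
#' @param lag base lag in ns.
#' @param stride_ns physical time per frame.
#' @param macro_sets list of integer vectors partitioning the active set
#'   (indices into the active-state ordering of the base model).
#' @param k_steps multiples of the base lag to test.
#' @param nboot bootstrap replicates for the error bars.
#' @param seed bootstrap seed.
#' @return data frame with predicted and estimated set-transition
#'   probabilities, bootstrap standard errors, and an `ok` flag.
#' @export
ck_test <- function(dtrajs, lag, stride_ns = 1, macro_sets, k_steps = 1:5,
                    nboot = 20L, seed = 1L) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  base <- markov_model(dtrajs, lag = lag, stride_ns = stride_ns)
  nset <- length(macro_sets)
  if (is.null(names(macro_sets)))
    names(macro_sets) <- paste0("S", seq_len(nset))
  setprob <- function(T, pi, k) {
    Tk <- diag(nrow(T))
    for (q in seq_len(k)) Tk <- Tk %*% T
    P <- matrix(NA_real_, nset, nset)
    for (a in seq_len(nset)) for (b in seq_len(nset)) {
      A <- macro_sets[[a]]; B <- macro_sets[[b]]
      w <- pi[A] / sum(pi[A])
      P[a, b] <- sum(w * rowSums(Tk[A, B, drop = FALSE]))
    }
    P
  }
  # set probabilities for a model whose active set may differ from the base:
  # macro sets are translated through the original state ids, dropping
  # states the re-estimated model does not resolve
  setprob_model <- function(m, pi_w, k) {
    P <- matrix(NA_real_, nset, nset)
    Tk <- diag(nrow(m$T))
    for (q in seq_len(k)) Tk <- Tk %*% m$T
    for (a in seq_len(nset)) for (b in seq_len(nset)) {
      A <- match(base$active[macro_sets[[a]]], m$active)
      B <- match(base$active[macro_sets[[b]]], m$active)
      wA <- pi_w[macro_sets[[a]]]
      keep <- !is.na(A)
      if (!any(keep)) return(NULL)
      A <- A[keep]; wA <- wA[keep] / sum(wA[keep])
      B <- B[!is.na(B)]
      P[a, b] <- sum(wA * rowSums(Tk[A, B, drop = FALSE]))
    }
    P
  }
  est_at <- function(dts, k) {
    m <- tryCatch(markov_model(dts, lag = k * lag, stride_ns = stride_ns),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    setprob_model(m, base$pi, 1L)
  }
  pred_at <- function(dts, k) {
    m <- tryCatch(markov_model(dts, lag = lag, stride_ns = stride_ns),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    setprob_model(m, base$pi, k)
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  rows <- list()
  for (k in k_steps) {
    P_pred <- setprob(base$T, base$pi, k)
    P_est <- est_at(dtrajs, k)
    ok <- !is.null(P_est)
    boot_p <- array(NA_real_, c(nset, nset, nboot))
    boot_e <- array(NA_real_, c(nset, nset, nboot))
    if (nboot > 0) {
      for (b in seq_len(nboot)) {
        idx <- sample.int(length(dtrajs), replace = TRUE)
        bp <- pred_at(dtrajs[idx], k)
        be <- est_at(dtrajs[idx], k)
        if (!is.null(bp)) boot_p[, , b] <- bp
        if (!is.null(be)) boot_e[, , b] <- be
      }
    }
    for (a in seq_len(nset)) for (bb in seq_len(nset)) {
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, lag_ns = k * lag,
        from = names(macro_sets)[a], to = names(macro_sets)[bb],
        predicted = P_pred[a, bb],
        estimated = if (ok) P_est[a, bb] else NA_real_,
        se_predicted = stats::sd(boot_p[a, bb, ], na.rm = TRUE),
        se_estimated = stats::sd(boot_e[a, bb, ], na.rm = TRUE),
        ok = ok)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ck_test", "data.frame")
  out
}
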