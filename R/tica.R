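#' Instantaneous and time-lagged covariances of pooled trajectories
#'
#' Mean-free covariance estimation pooled over all supplied trajectories
#' (including all symmetry-expanded rotation copies of one condition). The
#' lagged covariance is symmetrized as `(C + t(C)) / 2`, the standard
#' estimator when detailed balance is assumed.
#'
#' @param trajectories a [feature_trajectory()], bare matrix, or list of
#'   them; every trajectory must be longer than the lag.
#' @param lag lag time in the stride units of the trajectories (ns when the
#'   stride is in ns).
#' @return a list of class `tica_covariances` with `C0`, `Ct` (symmetrized),
#'   `means`, the lag in frames and in time units, and the frame count.
#' @export
estimate_covariances <- function(trajectories, lag) {
  trajs <- .as_traj_list(trajectories)
  stride <- attr(trajs[[1]], "stride")
  if (is.null(stride)) stride <- 1
  L <- lag / stride
  if (abs(L - round(L)) > 1e-9)
    stop("lag must be a multiple of the frame stride")
  L <- as.integer(round(L))
  F <- ncol(trajs[[1]])
  if (F < 2L) stop("need at least 2 features")
  ns <- vapply(trajs, nrow, 0L)
  if (any(ns <= L)) stop("every trajectory must be longer than the lag")
  ntot <- sum(ns)
  mu <- Reduce(`+`, lapply(trajs, function(x) colSums(.ft_matrix(x)))) / ntot
  C0 <- matrix(0, F, F)
  Ct <- matrix(0, F, F)
  npairs <- 0
  for (x in trajs) {
    xc <- sweep(.ft_matrix(x), 2, mu)
    C0 <- C0 + crossprod(xc)
    n <- nrow(xc)
    a <- xc[seq_len(n - L), , drop = FALSE]
    b <- xc[seq_len(n - L) + L, , drop = FALSE]
    Ct <- Ct + crossprod(a, b)
    npairs <- npairs + (n - L)
  }
  C0 <- C0 / ntot
  Ct <- Ct / npairs
  Ct <- (Ct + t(Ct)) / 2
  structure(list(C0 = C0, Ct = Ct, means = mu, lag_frames = L,
                 lag = lag, n_frames = ntot),
            class = "tica_covariances")
}

.as_traj_list <- function(x) {
  if (is.list(x) && !inherits(x, "feature_trajectory")) x else list(x)
}

#' Fit a time-lagged independent component model
#'
#' Solves the generalized eigenproblem `Ct v = lambda C0 v` on the
#' regularized subspace of `C0` (eigenvalue floor `1e-8 * trace(C0) / F`,
#' which absorbs the exact collinearity induced by pooled symmetry-expanded
#' copies). Eigenvectors are C0-orthonormal and eigenvalues are sorted in
#' decreasing order; a frame projects as the eigenvector dot its mean-free
#' features, scaled per component by the eigenvalue when kinetic mapping is
#' on (so Euclidean distances in projection space approximate kinetic
#' distances).
#'
#' @param covariances an [estimate_covariances()] result (or a list with
#'   `C0`, `Ct`, `means`).
#' @param n_dims number of components to retain (default: the full
#'   regularized rank, at least 2).
#' @param kinetic_map logical; scale projections by eigenvalues.
#' @param eps relative eigenvalue floor for the C0 regularization.
#' @return an object of class `tica` with eigenvalues, C0-orthonormal
#'   eigenvectors (columns), means, lag, and the retained dimension count.
#' @export
fit_tica <- function(covariances, n_dims = NULL, kinetic_map = TRUE,
                     eps = 1e-8) {
  C0 <- covariances$C0
  Ct <- covariances$Ct
  F <- ncol(C0)
  e0 <- eigen((C0 + t(C0)) / 2, symmetric = TRUE)
  floor_val <- eps * sum(diag(C0)) / F
  keep <- e0$values > floor_val
  if (!any(keep)) stop("C0 has no usable variance")
  regularized <- any(!keep)
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  M <- t(W) %*% Ct %*% W
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  lam <- em$values
  if (any(abs(lam) > 1 + 1e-8))
    warning("tICA eigenvalues exceed 1 beyond tolerance; data may violate stationarity")
  lam <- pmin(pmax(lam, -1), 1)
  if (max(lam) < 1e-6) stop("no slow process: all tICA eigenvalues near zero")
  V <- W %*% em$vectors
  rank <- length(lam)
  retained <- if (is.null(n_dims)) rank else min(as.integer(n_dims), rank)
  retained <- max(retained, min(2L, rank))
  structure(list(eigenvalues = lam, eigenvectors = V,
                 means = covariances$means, lag = covariances$lag,
                 kinetic_map = isTRUE(kinetic_map), rank = rank,
                 retained = retained, regularized = regularized),
            class = "tica")
}

#' One-call tICA estimation
#'
#' Convenience wrapper: [estimate_covariances()] followed by [fit_tica()].
#'
#' @inheritParams estimate_covariances
#' @inheritParams fit_tica
#' @param ... passed to [fit_tica()].
#' @return a `tica` model.
#' @export
tica <- function(trajectories, lag, ...) {
  fit_tica(estimate_covariances(trajectories, lag), ...)
}

#' @export
print.tica <- function(x, ...) {
  cat("tICA model: lag", x$lag, "ns,", x$rank, "components",
      if (x$regularized) "(rank-regularized)" else "", "\n")
  cat("  leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  cat("  kinetic mapping:", x$kinetic_map, "; retained dims:", x$retained, "\n")
  invisible(x)
}

#' @export
summary.tica <- function(object, ...) {
  lam <- object$eigenvalues
  ts <- .its_from_lambda(lam, object$lag)
  data.frame(component = seq_along(lam), eigenvalue = lam, timescale_ns = ts)
}

#' Project frames onto the independent components
#'
#' @param object a fitted [tica()] model.
#' @param newdata a [feature_trajectory()] or matrix of frames.
#' @param dims component indices (default: the retained dimensions).
#' @param ... unused.
#' @return projection matrix (frames x components).
#' @export
predict.tica <- function(object, newdata, dims = seq_len(object$retained),
                         ...) {
  X <- if (inherits(newdata, "feature_trajectory")) .ft_matrix(newdata)
       else as.matrix(newdata)
  Y <- sweep(X, 2, object$means) %*% object$eigenvectors[, dims, drop = FALSE]
  if (object$kinetic_map)
    Y <- sweep(Y, 2, object$eigenvalues[dims], `*`)
  Y
}

#' Retain slow dimensions whose marginals reject a single Gaussian
#'
#' Fast tICA dimensions whose projected marginal is described by a single
#' Gaussian carry no metastable structure and are omitted before
#' discretization. The test compares the BIC of 1- versus 2-component
#' univariate Gaussian mixtures (unequal variances): a dimension is kept
#' when the 2-component fit improves BIC by at least `delta_bic`. At least
#' two dimensions are always retained (falling back to the two slowest) so
#' a landscape can be plotted.
#'
#' @param projections matrix of projected frames, columns ordered slowest
#'   first.
#' @param delta_bic BIC margin required to reject the single Gaussian
#'   (default 10, decisive on the usual evidence scales).
#' @param max_points cap on the number of frames used per dimension (an
#'   evenly spaced deterministic subsample).
#' @return sorted integer indices of the retained dimensions.
#' @export
select_dimensions <- function(projections, delta_bic = 10, max_points = 5000L) {
  X <- as.matrix(projections)
  keep <- logical(ncol(X))
  for (d in seq_len(ncol(X))) {
    x <- X[, d]
    if (length(x) > max_points)
      x <- x[round(seq(1, length(x), length.out = max_points))]
    if (stats::sd(x) == 0) { keep[d] <- FALSE; next }
    fit <- tryCatch(
      mclust::mclustBIC(x, G = 1:2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) { keep[d] <- FALSE; next }
    b1 <- fit["1", "V"]; b2 <- fit["2", "V"]
    keep[d] <- is.finite(b1) && is.finite(b2) && (b2 - b1 >= delta_bic)
  }
  if (sum(keep) < 2L) keep[seq_len(min(2L, ncol(X)))] <- TRUE
  which(keep)
}
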