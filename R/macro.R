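#' PCCA+ coarse-graining of a Markov state model
#'
#' Perron cluster cluster analysis: the top `n_macro` right eigenvectors of
#' the reversible transition matrix span a simplex whose vertices correspond
#' to maximally metastable sets. Vertices are located by the inner-simplex
#' construction (iterative farthest-point search with orthogonal
#' deflation); memberships are the barycentric coordinates, clipped to
#' `[0, 1]` and row-renormalized. Crisp assignment takes the arg-max
#' membership, ties breaking toward the lower macrostate index.
#'
#' @param model an [markov_model()] fit.
#' @param n_macro number of macrostates (must not exceed the number of
#'   resolvable eigenvalues).
#' @return an object of class `macro_model`: membership matrix `chi`
#'   (microstates x macrostates), crisp `assignment`, stationary macrostate
#'   `populations`, the MFPT matrix between macrostates (microseconds), and
#'   a spectral-gap `warning` flag.
#' @export
pcca_macrostates <- function(model, n_macro = 2L) {
  stopifnot(inherits(model, "msm"))
  n_macro <- as.integer(n_macro)
  k <- nrow(model$T)
  if (n_macro < 1L || n_macro > k)
    stop("n_macro must be between 1 and the number of active microstates")
  if (n_macro == 1L) {
    chi <- matrix(1, k, 1)
    assignment <- rep(1L, k)
  } else {
    X <- model$eigenvectors[, seq_len(n_macro), drop = FALSE]
    X[, 1] <- 1
    chi <- .inner_simplex_memberships(X)
    assignment <- max.col(chi, ties.method = "first")
  }
  gap_warn <- FALSE
  lam <- model$eigenvalues
  if (n_macro > 1L && n_macro < length(lam)) {
    gap <- lam[n_macro] - lam[n_macro + 1]
    if (gap < 1e-3) {
      warning("no clear spectral gap after ", n_macro, " eigenvalues")
      gap_warn <- TRUE
    }
  }
  pops <- macro_populations(model$pi, assignment, n_macro)
  mf <- matrix(0, n_macro, n_macro)
  for (a in seq_len(n_macro)) for (b in seq_len(n_macro)) {
    if (a == b) next
    src <- which(assignment == a); tgt <- which(assignment == b)
    mf[a, b] <- tryCatch(
      mean_first_passage_time(model, src, tgt),
      error = function(e) NA_real_)
  }
  structure(list(chi = chi, assignment = assignment, populations = pops,
                 mfpt_us = mf, n_macro = n_macro, spectral_gap_warning = gap_warn,
                 lag = model$lag),
            class = "macro_model")
}

# inner-simplex vertex search on the eigenvector rows; returns clipped,
# row-normalized barycentric memberships
.inner_simplex_memberships <- function(X) {
  n <- nrow(X); m <- ncol(X)
  vertices <- integer(m)
  Y <- X
  vertices[1] <- which.max(rowSums(Y^2))
  Y <- sweep(Y, 2, X[vertices[1], ])
  for (j in 2:m) {
    d <- rowSums(Y^2)
    vertices[j] <- which.max(d)
    v <- Y[vertices[j], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) {
      # degenerate: eigenvector rows do not span the simplex
      vertices[j:m] <- setdiff(order(rowSums(X^2), decreasing = TRUE),
                               vertices[seq_len(j - 1)])[seq_len(m - j + 1)]
      break
    }
    v <- v / nv
    Y <- Y - outer(as.vector(Y %*% v), v)
  }
  A <- solve(X[vertices, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi[chi > 1] <- 1
  sweep(chi, 1, rowSums(chi), `/`)
}

#' @export
print.macro_model <- function(x, ...) {
  cat("PCCA+ macrostate model:", x$n_macro, "macrostates\n")
  cat("  populations:", paste(signif(x$populations, 4), collapse = ", "), "\n")
  if (x$n_macro > 1) {
    cat("  MFPT matrix (us):\n")
    print(signif(x$mfpt_us, 4))
  }
  invisible(x)
}

#' Stationary macrostate populations
#'
#' @param pi microstate stationary distribution.
#' @param assignment crisp macrostate index per microstate.
#' @param n_macro number of macrostates (default: maximum assignment).
#' @return numeric vector of population fractions (sums to 1).
#' @export
macro_populations <- function(pi, assignment, n_macro = max(assignment)) {
  vapply(seq_len(n_macro), function(a) sum(pi[assignment == a]), 0)
}

#' Mean first-passage time between microstate sets
#'
#' Solves `m_i = tau + sum_j T_ij m_j` for `i` outside the target set with
#' `m = 0` on the target, then averages over the source set with stationary
#' weights restricted to the source. Reported in microseconds.
#'
#' @param model an [markov_model()] fit.
#' @param source_set,target_set disjoint, nonempty index vectors into the
#'   active-state ordering.
#' @return MFPT in microseconds.
#' @export
mean_first_passage_time <- function(model, source_set, target_set) {
  stopifnot(inherits(model, "msm"))
  T <- model$T
  n <- nrow(T)
  source_set <- as.integer(source_set); target_set <- as.integer(target_set)
  if (length(source_set) == 0L || length(target_set) == 0L)
    stop("source and target sets must be nonempty")
  if (length(intersect(source_set, target_set)) > 0L)
    stop("source and target sets must be disjoint")
  if (any(c(source_set, target_set) < 1L) || any(c(source_set, target_set) > n))
    stop("state indices outside the active set")
  keep <- setdiff(seq_len(n), target_set)
  A <- diag(length(keep)) - T[keep, keep, drop = FALSE]
  m <- numeric(n)
  sol <- tryCatch(solve(A, rep(model$lag, length(keep))),
                  error = function(e) stop("target set unreachable from source"))
  if (any(!is.finite(sol)) || any(sol < 0))
    stop("target set unreachable from source")
  m[keep] <- sol
  w <- model$pi[source_set] / sum(model$pi[source_set])
  sum(w * m[source_set]) / 1000
}

#' Stationary-reweighted free-energy landscape over two tICA coordinates
#'
#' Each frame is weighted by `pi_s / n_s` (the stationary probability of its
#' microstate divided by the number of frames observed in that microstate),
#' so the weighted 2D histogram estimates the equilibrium density even
#' though the seeded trajectories are far from equilibrium. The free energy
#' is `-kT * log(density / max density)`, so the minimum over populated bins
#' is exactly 0; empty bins are masked (`NA`), never assigned a value.
#' Frames in states outside the active set are excluded and counted.
#'
#' @param projections frames x >=2 projection matrix (or list matching the
#'   model's trajectories), first two columns used.
#' @param model an [markov_model()] fit whose discrete trajectories align
#'   frame-by-frame with `projections`.
#' @param bins number of bins per axis (default 80).
#' @param kT thermal energy in kcal/mol (default 0.5962, i.e. 300 K).
#' @return object of class `free_energy_landscape`: bin edges, `dG` matrix
#'   (kcal/mol, NA for empty bins), the per-frame weights and first-axis
#'   values (used for barrier profiles), and the excluded-frame count.
#' @export
free_energy_landscape <- function(projections, model, bins = 80L,
                                  kT = 0.5962) {
  stopifnot(inherits(model, "msm"))
  P <- if (is.list(projections)) do.call(rbind, projections)
       else as.matrix(projections)
  if (ncol(P) < 2L) stop("need at least two projected dimensions")
  s <- unlist(model$dtrajs, use.names = FALSE)
  if (length(s) != nrow(P))
    stop("projections and model trajectories differ in frame count")
  ok <- !is.na(s)
  excluded <- sum(!ok)
  P <- P[ok, 1:2, drop = FALSE]
  s <- s[ok]
  nst <- tabulate(s, nbins = nrow(model$T))
  w <- model$pi[s] / nst[s]
  w <- w / sum(w)
  xe <- seq(min(P[, 1]), max(P[, 1]), length.out = bins + 1L)
  ye <- seq(min(P[, 2]), max(P[, 2]), length.out = bins + 1L)
  bx <- pmin(pmax(findInterval(P[, 1], xe, rightmost.closed = TRUE), 1L), bins)
  by <- pmin(pmax(findInterval(P[, 2], ye, rightmost.closed = TRUE), 1L), bins)
  dens <- matrix(tabulate2(bx + (by - 1L) * bins, w, bins * bins),
                 bins, bins)
  dG <- matrix(NA_real_, bins, bins)
  pos <- dens > 0
  dG[pos] <- -kT * log(dens[pos] / max(dens))
  structure(list(x_edges = xe, y_edges = ye, dG = dG, kT = kT,
                 density = dens, frames = list(x = P[, 1], w = w),
                 excluded_frames = excluded),
            class = "free_energy_landscape")
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat("free_energy_landscape:", nrow(x$dG), "x", ncol(x$dG), "bins, kT =",
      x$kT, "kcal/mol;", sum(!is.na(x$dG)), "populated bins\n")
  invisible(x)
}

#' @export
plot.free_energy_landscape <- function(x, ...) {
  z <- x$dG
  graphics::image(x = (x$x_edges[-1] + x$x_edges[-length(x$x_edges)]) / 2,
                  y = (x$y_edges[-1] + x$y_edges[-length(x$y_edges)]) / 2,
                  z = z, xlab = "tIC 1", ylab = "tIC 2",
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE), ...)
  invisible(x)
}

#' Free-energy barrier between two macrostates along the first coordinate
#'
#' Builds the stationary-weighted 1D free-energy profile along the first
#' landscape axis, locates the profile minimum of each macrostate (over the
#' bins that macrostate dominates by weight), and returns the maximum of
#' the profile over populated bins between the two minima, measured from
#' the deeper (source) minimum.
#'
#' @param landscape a [free_energy_landscape()].
#' @param macro_frames crisp macrostate label per frame of the landscape
#'   (frames in excluded states must already be dropped); exactly two
#'   distinct labels required.
#' @param bins number of profile bins (default: landscape bin count).
#' @return barrier height in kcal/mol.
#' @export
barrier_height <- function(landscape, macro_frames,
                           bins = length(landscape$x_edges) - 1L) {
  x <- landscape$frames$x
  w <- landscape$frames$w
  macro_frames <- as.integer(factor(macro_frames))
  if (length(macro_frames) != length(x))
    stop("macro_frames must label every landscape frame")
  if (length(unique(macro_frames)) != 2L)
    stop("exactly two macrostates required")
  kT <- landscape$kT
  xe <- seq(min(x), max(x), length.out = bins + 1L)
  bx <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1L), bins)
  dens <- tabulate2(bx, w, bins)
  w1 <- tabulate2(bx[macro_frames == 1L], w[macro_frames == 1L], bins)
  w2 <- tabulate2(bx[macro_frames == 2L], w[macro_frames == 2L], bins)
  G <- ifelse(dens > 0, -kT * log(dens / max(dens)), NA_real_)
  dom1 <- which(dens > 0 & w1 >= w2)
  dom2 <- which(dens > 0 & w2 > w1)
  if (length(dom1) == 0L || length(dom2) == 0L)
    stop("minima not separated: a macrostate dominates no bins")
  m1 <- dom1[which.min(G[dom1])]
  m2 <- dom2[which.min(G[dom2])]
  lo <- min(m1, m2); hi <- max(m1, m2)
  if (hi - lo < 2L) stop("minima not separated along the profile")
  between <- (lo + 1L):(hi - 1L)
  between <- between[!is.na(G[between])]
  if (length(between) == 0L) stop("minima not separated: no populated bins between them")
  source_min <- min(G[m1], G[m2])
  max(G[between]) - source_min
}

#' Open-probability elbow scan over clustering and lag hyperparameters
#'
#' Runs the discretization-MSM-PCCA+ pipeline for every combination of
#' microstate count and lag, records the open-macrostate population (the
#' two-state macrostate with the higher mean first-coordinate, i.e. the
#' open-like side of the landscape), and selects the elbow: the smallest
#' cluster count beyond which the open population changes by less than
#' `tol` between successive grid points at every lag. If no flat region
#' exists the largest cluster count is returned with a warning.
#'
#' @param projections list of per-trajectory projection matrices.
#' @param cluster_grid increasing vector of microstate counts.
#' @param lag_grid lag times in frames.
#' @param stride_ns physical time per frame (ns).
#' @param seed k-means seed.
#' @param tol elbow flatness tolerance on the open population.
#' @param nstart k-means restarts per grid point.
#' @param fit_sample frames used for center fitting (see
#'   [cluster_microstates()]).
#' @return list with the scan `table` (k, lag_ns, p_open), the `elbow_k`
#'   choice and a `flat` flag.
#' @export
hyperparameter_scan <- function(projections, cluster_grid, lag_grid = 1L,
                                stride_ns = 1, seed = 1L, tol = 0.01,
                                nstart = 3L, fit_sample = 50000L) {
  if (!is.list(projections)) projections <- list(projections)
  cluster_grid <- sort(unique(as.integer(cluster_grid)))
  rows <- list()
  for (k in cluster_grid) {
    cl <- cluster_microstates(projections, k = k, seed = seed,
                              nstart = nstart, fit_sample = fit_sample)
    for (lagf in lag_grid) {
      p_open <- tryCatch({
        m <- markov_model(cl$dtrajs, lag = lagf * stride_ns,
                          stride_ns = stride_ns, centers = cl$centers)
        mac <- suppressWarnings(pcca_macrostates(m, 2L))
        # open macrostate: higher mean tIC1 over member microstates
        tic1 <- vapply(1:2, function(a) {
          mem <- which(mac$assignment == a)
          sum(m$pi[mem] * m$centers[mem, 1]) / sum(m$pi[mem])
        }, 0)
        mac$populations[which.max(tic1)]
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(k = k, lag_ns = lagf * stride_ns,
                                              p_open = p_open)
    }
  }
  tab <- do.call(rbind, rows)
  elbow_k <- NA_integer_
  flat <- FALSE
  if (length(cluster_grid) >= 2L) {
    for (i in seq_len(length(cluster_grid) - 1L)) {
      ks <- cluster_grid[i:(i + 1L)]
      d <- vapply(unique(tab$lag_ns), function(l) {
        p1 <- tab$p_open[tab$lag_ns == l & tab$k == ks[1]]
        p2 <- tab$p_open[tab$lag_ns == l & tab$k == ks[2]]
        abs(p2 - p1)
      }, 0)
      if (all(is.finite(d)) && all(d < tol)) {
        elbow_k <- cluster_grid[i]
        flat <- TRUE
        break
      }
    }
  }
  if (!flat) {
    elbow_k <- cluster_grid[length(cluster_grid)]
    if (length(cluster_grid) > 1L)
      warning("no flat region in the open-probability scan; returning largest k")
  }
  list(table = tab, elbow_k = elbow_k, flat = flat)
}
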