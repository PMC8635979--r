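#' Build an elastic network model from a labeled structure
#'
#' Edges connect every bead pair within the applicable cutoff — by default
#' 12 Angstrom for pairs within one subunit and 8 Angstrom across subunits —
#' with rest lengths equal to the build-time distances and a single uniform
#' force constant (default 10 kcal/(mol A^2)).
#'
#' @param structure a [coarse_structure()] with subunit labels.
#' @param intra_cutoff,inter_cutoff cutoff distances (Angstrom).
#' @param k harmonic force constant, kcal/(mol A^2).
#' @return an object of class `elastic_network` with edge list `(i, j)`,
#'   rest lengths `r0`, intra-subunit flags and `k`.
#' @export
build_network <- function(structure, intra_cutoff = 12, inter_cutoff = 8,
                          k = 10) {
  stopifnot(inherits(structure, "coarse_structure"))
  if (intra_cutoff <= 0 || inter_cutoff <= 0) stop("cutoffs must be positive")
  sub <- structure$atoms$subunit
  if (is.null(sub) || anyNA(sub))
    stop("structure lacks subunit labels; intra/inter edges undecidable")
  X <- structure$xyz
  n <- nrow(X)
  if (n < 2L) stop("need at least two beads")
  D <- as.matrix(stats::dist(X))
  same <- outer(sub, sub, "==")
  cut <- ifelse(same, intra_cutoff, inter_cutoff)
  sel <- which(upper.tri(D) & D <= cut & D > 0, arr.ind = TRUE)
  if (nrow(sel) == 0L) stop("no edges within cutoffs")
  structure(list(i = sel[, 1], j = sel[, 2],
                 r0 = D[sel], intra = same[sel], k = k, n_nodes = n),
            class = "elastic_network")
}

#' @export
print.elastic_network <- function(x, ...) {
  cat("elastic_network:", x$n_nodes, "nodes,", length(x$i), "edges",
      sprintf("(%d intra, %d inter),", sum(x$intra), sum(!x$intra)),
      "k =", x$k, "kcal/(mol A^2)\n")
  invisible(x)
}

#' Harmonic elastic-network energy
#'
#' @param network an [build_network()] result.
#' @param xyz n x 3 coordinates (defaults extracted from a
#'   [coarse_structure()]).
#' @return energy in kcal/mol.
#' @export
enm_energy <- function(network, xyz) {
  if (inherits(xyz, "coarse_structure")) xyz <- xyz$xyz
  d <- sqrt(rowSums((xyz[network$j, , drop = FALSE] -
                     xyz[network$i, , drop = FALSE])^2))
  0.5 * network$k * sum((d - network$r0)^2)
}

# rms deviation between the internal (all-pairs) distances of two coordinate
# sets; the driving objective of the pathway generator
internal_distance_rms <- function(a, b) {
  if (inherits(a, "coarse_structure")) a <- a$xyz
  if (inherits(b, "coarse_structure")) b <- b$xyz
  da <- stats::dist(a); db <- stats::dist(b)
  sqrt(mean((da - db)^2))
}

#' Elastic-network plus target-bias forces
#'
#' The force on each bead is the sum of (i) harmonic elastic-network
#' restoring forces about the edge rest lengths and (ii) a harmonic bias on
#' the fraction `bias_fraction` of all bead pairs whose current internal
#' distance deviates most from the target's, pulling those distances toward
#' the target values. Pair forces are equal and opposite, so the net force
#' is always zero.
#'
#' @param current,target n x 3 coordinate matrices (or
#'   [coarse_structure()]s) with matching bead order.
#' @param network an [build_network()] result.
#' @param bias_fraction fraction in (0, 1] of worst-matching pairs to bias.
#' @param k_bias bias force constant (defaults to the network constant).
#' @return n x 3 matrix of forces, kcal/(mol A).
#' @export
driving_forces <- function(current, target, network, bias_fraction = 0.1,
                           k_bias = network$k) {
  if (inherits(current, "coarse_structure")) current <- current$xyz
  if (inherits(target, "coarse_structure")) target <- target$xyz
  if (!identical(dim(current), dim(target)))
    stop("current and target node counts differ")
  if (bias_fraction <= 0 || bias_fraction > 1)
    stop("bias_fraction must be in (0, 1]")
  n <- nrow(current)
  F <- matrix(0, n, 3)
  # elastic network term
  F <- .accumulate_forces(F, network$i, network$j,
                          .pair_contrib(current, network$i, network$j,
                                        network$k, network$r0))
  # bias term on worst-matching internal distances
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pi_ <- pairs[, 1]; pj <- pairs[, 2]
  dc <- sqrt(rowSums((current[pj, , drop = FALSE] -
                      current[pi_, , drop = FALSE])^2))
  dt <- sqrt(rowSums((target[pj, , drop = FALSE] -
                      target[pi_, , drop = FALSE])^2))
  nb <- max(1L, ceiling(bias_fraction * length(dc)))
  worst <- order(abs(dc - dt), decreasing = TRUE)[seq_len(nb)]
  F <- .accumulate_forces(F, pi_[worst], pj[worst],
                          .pair_contrib(current, pi_[worst], pj[worst],
                                        k_bias, dt[worst]))
  F
}

# force contribution on node i from harmonic pair (i, j) about rest length
.pair_contrib <- function(X, i, j, k, rest) {
  v <- X[j, , drop = FALSE] - X[i, , drop = FALSE]
  d <- sqrt(rowSums(v * v))
  v * (k * (d - rest) / pmax(d, 1e-12))
}

.accumulate_forces <- function(F, i, j, contrib) {
  for (c in 1:3) {
    F[, c] <- F[, c] +
      tabulate2(i, contrib[, c], nrow(F)) - tabulate2(j, contrib[, c], nrow(F))
  }
  F
}

# sum `w` into bins `idx` of length n (weighted tabulate)
tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx, reorder = FALSE)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Drive a structure between conformations with biased Brownian dynamics
#'
#' Overdamped Langevin dynamics on an elastic network built from the start
#' structure, with a harmonic bias that progressively minimizes the
#' difference in internal distances between the current and target states
#' (see [driving_forces()]). Network rest lengths are refreshed to the
#' current geometry every `refresh_every` steps, so the network maintains
#' local structure while the bias drives the transition. The run terminates
#' when the all-pairs internal-distance RMS to the target drops below `tol`,
#' or at `max_steps` (returned with `converged = FALSE` and a warning).
#'
#' @param start,target [coarse_structure()]s with matching topology.
#' @param dt integration step (reduced time units).
#' @param friction friction coefficient (reduced units).
#' @param kT thermal energy (kcal/mol) of the Brownian noise.
#' @param bias_fraction fraction of worst-matching pairs biased per step.
#' @param max_steps step cap.
#' @param seed integer seed (runs are bit-reproducible given the seed).
#' @param tol convergence tolerance on the internal-distance RMS (Angstrom).
#' @param refresh_every rest-length refresh interval (steps).
#' @param record_every frame recording stride (steps).
#' @param max_disp cap on the per-step drift displacement (Angstrom).
#' @param intra_cutoff,inter_cutoff,k network parameters, see
#'   [build_network()].
#' @return an object of class `pathway_ensemble`: recorded frames, the
#'   per-frame normalized transition progress (0 at the start value, 1 at
#'   convergence, non-decreasing), internal-distance RMS to target, and a
#'   `converged` flag.
#' @export
run_ebdims <- function(start, target, dt = 0.002, friction = 1, kT = 0.1,
                       bias_fraction = 0.1, max_steps = 20000L, seed = 1L,
                       tol = 0.5, refresh_every = 50L, record_every = 1L,
                       max_disp = 0.05, intra_cutoff = 12, inter_cutoff = 8,
                       k = 10) {
  stopifnot(inherits(start, "coarse_structure"),
            inherits(target, "coarse_structure"))
  if (!identical(dim(start$xyz), dim(target$xyz)))
    stop("start and target topologies differ")
  if (dt <= 0 || friction <= 0 || kT < 0 || max_steps < 1)
    stop("integrator parameters must be positive")
  net <- build_network(start, intra_cutoff, inter_cutoff, k)
  X <- start$xyz
  Xt <- target$xyz
  n <- nrow(X)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  noise_scale <- sqrt(2 * kT * dt / friction)
  frames <- list(X)
  rms <- internal_distance_rms(X, Xt)
  rms_trace <- rms
  converged <- rms < tol
  step <- 0L
  while (!converged && step < max_steps) {
    step <- step + 1L
    F <- driving_forces(X, Xt, net, bias_fraction = bias_fraction)
    drift <- F * dt / friction
    dn <- sqrt(rowSums(drift^2))
    over <- dn > max_disp
    if (any(over)) drift[over, ] <- drift[over, ] * (max_disp / dn[over])
    X <- X + drift + matrix(stats::rnorm(3L * n, sd = noise_scale), n, 3L)
    if (step %% refresh_every == 0L) {
      d <- sqrt(rowSums((X[net$j, , drop = FALSE] -
                         X[net$i, , drop = FALSE])^2))
      net$r0 <- d
    }
    rms <- internal_distance_rms(X, Xt)
    if (step %% record_every == 0L) {
      frames[[length(frames) + 1L]] <- X
      rms_trace <- c(rms_trace, rms)
    }
    if (rms < tol) converged <- TRUE
  }
  if (converged && (length(rms_trace) == 0L ||
                    rms_trace[length(rms_trace)] > rms)) {
    frames[[length(frames) + 1L]] <- X
    rms_trace <- c(rms_trace, rms)
  }
  if (!converged)
    warning("run_ebdims did not converge within max_steps (final RMS ",
            signif(rms, 3), " A); returning partial ensemble")
  rms0 <- rms_trace[1]
  rmsF <- rms_trace[length(rms_trace)]
  progress <- if (abs(rms0 - rmsF) < 1e-12) rep(0, length(rms_trace))
              else pmin(pmax(cummax((rms0 - rms_trace) / (rms0 - rmsF)), 0), 1)
  structure(list(frames = frames, progress = progress, rms = rms_trace,
                 converged = converged, template = start, seed = seed,
                 n_steps = step),
            class = "pathway_ensemble")
}

#' @export
print.pathway_ensemble <- function(x, ...) {
  cat("pathway_ensemble:", length(x$frames), "frames,",
      x$n_steps, "integration steps,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(final internal-distance RMS %.3g A)\n", x$rms[length(x$rms)]))
  invisible(x)
}

#' Select evenly spaced seed structures from forward and reverse pathways
#'
#' Picks `n_seeds/2` frames per direction at approximately equal spacing of
#' the transition-progress coordinate, endpoints included, to obtain initial
#' models interspersed along the gating transition.
#'
#' @param forward,reverse [run_ebdims()] ensembles for the two directions.
#' @param n_seeds total number of seeds (default 50; must be even).
#' @return list of [coarse_structure()] seeds with a `manifest` attribute
#'   (data frame: seed id, direction, progress).
#' @export
select_seeds <- function(forward, reverse, n_seeds = 50L) {
  n_seeds <- as.integer(n_seeds)
  if (n_seeds %% 2L != 0L) stop("n_seeds must be even")
  half <- n_seeds %/% 2L
  pick <- function(ens, direction) {
    if (length(ens$frames) < half)
      stop("pathway too short: ", length(ens$frames), " frames < ", half,
           " seeds requested for the ", direction, " direction")
    targets <- seq(0, 1, length.out = half)
    idx <- vapply(targets, function(p) which.min(abs(ens$progress - p)), 0L)
    idx <- sort(idx)
    lapply(seq_along(idx), function(q) {
      s <- ens$template
      coords(s) <- ens$frames[[idx[q]]]
      attr(s, "progress") <- ens$progress[idx[q]]
      attr(s, "direction") <- direction
      s
    })
  }
  seeds <- c(pick(forward, "forward"), pick(reverse, "reverse"))
  manifest <- data.frame(
    seed = seq_along(seeds),
    direction = vapply(seeds, attr, "", "direction"),
    progress = vapply(seeds, attr, 0, "progress"))
  attr(seeds, "manifest") <- manifest
  seeds
}

#' Write pathway seeds as a multi-model PDB with a CSV manifest
#'
#' @param seeds result of [select_seeds()].
#' @param pdb_file output multi-model PDB path.
#' @param manifest_file output CSV path (default: `pdb_file` with a
#'   `.csv` extension).
#' @return `pdb_file`, invisibly.
#' @export
write_seeds_pdb <- function(seeds, pdb_file,
                            manifest_file = sub("\\.pdb$", ".csv", pdb_file)) {
  con <- file(pdb_file, "w")
  on.exit(close(con))
  for (m in seq_along(seeds)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    tmp <- tempfile(fileext = ".pdb")
    write_structure_pdb(seeds[[m]], tmp)
    lines <- readLines(tmp)
    writeLines(lines[startsWith(lines, "ATOM")], con)
    unlink(tmp)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  utils::write.csv(attr(seeds, "manifest"), manifest_file, row.names = FALSE)
  invisible(pdb_file)
}
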