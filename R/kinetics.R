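#' Ground-truth Markov kinetics for synthetic trajectories
#'
#' Bundles a row-stochastic microstate transition matrix with its lag time,
#' a microstate-to-macrostate map and a Gaussian emission model. Synthetic
#' feature trajectories drawn from this object have exactly known stationary
#' distribution, implied timescales, macrostate populations and mean
#' first-passage times (see [ground_truth_reference()]), so every downstream
#' estimator can be validated by parameter recovery.
#'
#' @param transition_matrix square row-stochastic matrix (rows sum to 1
#'   within 1e-12); must be irreducible.
#' @param lag physical time per transition step (ns).
#' @param macro_map character vector, one label (`"closed"`/`"open"`) per
#'   microstate.
#' @param emission_means matrix, one row per microstate: mean feature vector
#'   emitted per subunit block.
#' @param emission_sd standard deviation of the iid Gaussian emission noise
#'   (>= 0).
#' @return an object of class `ground_truth_kinetics`.
#' @export
ground_truth_kinetics <- function(transition_matrix, lag = 20,
                                  macro_map = NULL, emission_means = NULL,
                                  emission_sd = 0.2) {
  T <- as.matrix(transition_matrix)
  n <- nrow(T)
  if (ncol(T) != n) stop("transition matrix must be square")
  if (any(T < 0)) stop("transition matrix must be non-negative")
  if (any(abs(rowSums(T) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1 (within 1e-12)")
  .check_irreducible(T)
  if (is.null(macro_map)) macro_map <- rep("closed", n)
  if (length(macro_map) != n) stop("macro_map must have one label per state")
  if (!is.null(emission_means)) {
    emission_means <- as.matrix(emission_means)
    if (nrow(emission_means) != n)
      stop("emission_means must have one row per state")
  }
  if (emission_sd < 0) stop("emission_sd must be >= 0")
  structure(list(T = T, lag = lag, macro_map = macro_map,
                 emission_means = emission_means, emission_sd = emission_sd),
            class = "ground_truth_kinetics")
}

.check_irreducible <- function(T) {
  g <- igraph::graph_from_adjacency_matrix((T > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1L) {
    sets <- split(seq_len(nrow(T)), comp$membership)
    stop("transition matrix is reducible; disconnected sets: ",
         paste(vapply(sets, function(s) paste0("{", paste(s, collapse = ","), "}"),
                      ""), collapse = " "))
  }
  invisible(TRUE)
}

#' @export
print.ground_truth_kinetics <- function(x, ...) {
  cat("ground_truth_kinetics:", nrow(x$T), "microstates, lag", x$lag, "ns,",
      "macrostates:", paste(unique(x$macro_map), collapse = "/"), "\n")
  invisible(x)
}

#' Default two-basin ground truth
#'
#' Four microstates arranged as two metastable pairs (closed: states 1-2,
#' open: states 3-4) with intra-pair exchange probability 0.1 and total
#' inter-pair probability 0.005 per 20 ns lag step, mirroring the two-basin
#' free-energy landscapes of gating channels: fast motion within each basin,
#' rare barrier crossings between them. Emission means replicate a
#' three-feature pattern over five homologous subunit blocks; the first
#' feature separates the basins (the slow coordinate) and the second the
#' states within a basin.
#'
#' @param emission_sd Gaussian emission noise (default 0.2, i.e. five times
#'   smaller than the basin separation).
#' @return a [ground_truth_kinetics()].
#' @export
default_kinetics <- function(emission_sd = 0.2) {
  intra <- 0.1
  inter <- 0.005
  T <- matrix(inter / 2, 4, 4)
  T[1, 2] <- T[2, 1] <- T[3, 4] <- T[4, 3] <- intra
  diag(T) <- 0
  diag(T) <- 1 - rowSums(T)
  means <- rbind(c(-1, -0.5,  0.0),
                 c(-1,  0.5,  0.1),
                 c( 1, -0.5, -0.1),
                 c( 1,  0.5,  0.0))
  ground_truth_kinetics(T, lag = 20,
                        macro_map = c("closed", "closed", "open", "open"),
                        emission_means = means, emission_sd = emission_sd)
}

#' Sample a discrete state sequence from ground-truth kinetics
#'
#' @param kinetics a [ground_truth_kinetics()] (or a bare row-stochastic
#'   matrix).
#' @param n_steps length of the returned sequence (the start state counts as
#'   the first entry).
#' @param start_state 1-based starting microstate.
#' @param seed integer seed fixing the random stream.
#' @return integer vector of 1-based states, length `n_steps`.
#' @export
sample_markov_chain <- function(kinetics, n_steps, start_state = 1L, seed = 1L) {
  T <- if (inherits(kinetics, "ground_truth_kinetics")) kinetics$T
       else as.matrix(kinetics)
  n <- nrow(T)
  if (any(T < 0) || any(abs(rowSums(T) - 1) > 1e-12))
    stop("transition matrix must be row-stochastic")
  if (start_state < 1L || start_state > n) stop("start_state out of range")
  cum <- t(apply(T, 1, cumsum))
  states <- integer(n_steps)
  states[1] <- as.integer(start_state)
  if (n_steps > 1L) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    u <- stats::runif(n_steps - 1L)
    s <- states[1]
    for (t in 2:n_steps) {
      s <- findInterval(u[t - 1L], cum[s, ]) + 1L
      if (s > n) s <- n  # guard rounding at u ~ 1
      states[t] <- s
    }
  }
  states
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Emit feature vectors along a state sequence
#'
#' Per-frame features are the state's emission mean replicated over
#' `n_subunit_blocks` homologous blocks plus iid Gaussian noise, emulating
#' (at toy scale) the block structure of per-subunit interatomic-distance
#' features of a homopentamer.
#'
#' @param states integer state sequence (see [sample_markov_chain()]).
#' @param kinetics a [ground_truth_kinetics()] with `emission_means`.
#' @param n_subunit_blocks number of homologous feature blocks (default 5).
#' @param seed integer seed for the emission noise.
#' @return a [feature_trajectory()] of dimension
#'   `length(states) x (ncol(emission_means) * n_subunit_blocks)`; the frame
#'   stride is the kinetics lag.
#' @export
emit_features <- function(states, kinetics, n_subunit_blocks = 5L, seed = 1L) {
  stopifnot(inherits(kinetics, "ground_truth_kinetics"))
  if (is.null(kinetics$emission_means))
    stop("kinetics has no emission means")
  n_states <- nrow(kinetics$emission_means)
  states <- as.integer(states)
  if (any(states < 1L | states > n_states))
    stop("state index outside the emission table")
  block <- kinetics$emission_means
  means <- do.call(cbind, rep(list(block), n_subunit_blocks))
  X <- means[states, , drop = FALSE]
  if (kinetics$emission_sd > 0) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    X <- X + matrix(stats::rnorm(length(X), sd = kinetics$emission_sd),
                    nrow(X), ncol(X))
  }
  feature_trajectory(X, stride = kinetics$lag, n_blocks = n_subunit_blocks,
                     seed_id = seed)
}

#' Exact reference quantities of a ground-truth chain
#'
#' Closed-form/linear-algebra values used as the oracle for parameter
#' recovery: stationary distribution, implied timescales, macrostate
#' populations, and the macrostate mean first-passage-time matrix (same time
#' unit as the lag). MFPTs average the per-microstate first-passage times
#' over the source set with stationary weights.
#'
#' @param kinetics a [ground_truth_kinetics()].
#' @return a list with elements `pi`, `implied_timescales` (ns, slowest
#'   first, excluding the stationary process), `macro_populations` and
#'   `macro_mfpt` (matrix, ns).
#' @export
ground_truth_reference <- function(kinetics) {
  stopifnot(inherits(kinetics, "ground_truth_kinetics"))
  T <- kinetics$T
  .check_irreducible(T)
  pi <- stationary_distribution(T)
  ev <- sort(Re(eigen(T, only.values = TRUE)$values), decreasing = TRUE)
  lam <- ev[-1]
  its <- .its_from_lambda(lam, kinetics$lag)
  macro <- kinetics$macro_map
  labs <- unique(macro)
  pops <- vapply(labs, function(l) sum(pi[macro == l]), 0)
  mf <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (a in labs) for (b in labs) {
    if (a == b) next
    mf[a, b] <- .exact_mfpt(T, pi, which(macro == a), which(macro == b),
                            kinetics$lag)
  }
  list(pi = pi, implied_timescales = its, macro_populations = pops,
       macro_mfpt = mf)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Leading left eigenvector, normalized to sum to 1.
#'
#' @param T row-stochastic matrix.
#' @return numeric probability vector.
#' @export
stationary_distribution <- function(T) {
  e <- eigen(t(T))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) v <- abs(v)
  v / sum(v)
}

# first-passage time from source set into target set, pi-weighted over source
.exact_mfpt <- function(T, pi, source, target, lag) {
  n <- nrow(T)
  keep <- setdiff(seq_len(n), target)
  m <- numeric(n)
  A <- diag(length(keep)) - T[keep, keep, drop = FALSE]
  m[keep] <- solve(A, rep(lag, length(keep)))
  w <- pi[source] / sum(pi[source])
  sum(w * m[source])
}
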