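#' Configuration of an end-to-end gating analysis run
#'
#' Collects every tunable of the pipeline: the condition label, the input
#' (a synthetic ground truth or per-trajectory feature CSV files), the
#' trajectory ensemble size, tICA/MSM lags, microstate count, macrostate
#' counts, exclusions, the master seed and the thermal energy. Defaults
#' reproduce the package's standard synthetic study: 50 seeded trajectories
#' of 20,000 steps from the default two-basin ground truth, 20 ns lags, and
#' a 75-microstate discretization (the elbow region of the open-probability
#' scan for this generator).
#'
#' @param condition free-form label (e.g. variant x protonation).
#' @param kinetics a [ground_truth_kinetics()] for synthetic input, or NULL
#'   when `feature_files` is given.
#' @param feature_files optional character vector of feature CSV paths (see
#'   [write_feature_csv()]); overrides synthetic generation.
#' @param n_trajectories number of seeded trajectories.
#' @param n_steps frames per trajectory.
#' @param expand_blocks logical; apply the 5-fold cyclic block expansion to
#'   every trajectory before estimation.
#' @param tica_lag_ns tICA lag (ns).
#' @param n_tica_dims cap on retained tICA dimensions (NULL = automatic
#'   single-Gaussian pruning).
#' @param cluster_k number of k-means microstates.
#' @param kmeans_restarts,fit_sample k-means restarts and center-fitting
#'   subsample (see [cluster_microstates()]).
#' @param msm_lag_ns MSM lag (ns).
#' @param n_macro macrostate counts to build (first entry must be 2).
#' @param exclude integer indices of trajectories to exclude (audited in
#'   the output).
#' @param its_lags implied-timescale lags, in multiples of the frame
#'   stride.
#' @param ck_steps Chapman-Kolmogorov lag multiples.
#' @param ck_boot bootstrap replicates for CK error bars.
#' @param bins landscape bins per axis.
#' @param kT thermal energy (kcal/mol).
#' @param seed master seed; all stage streams derive from it
#'   deterministically.
#' @return an object of class `run_config`.
#' @export
run_config <- function(condition = "synthetic-default",
                       kinetics = default_kinetics(),
                       feature_files = NULL,
                       n_trajectories = 50L, n_steps = 20000L,
                       expand_blocks = FALSE,
                       tica_lag_ns = 20, n_tica_dims = NULL,
                       cluster_k = 75L, kmeans_restarts = 5L,
                       fit_sample = 200000L,
                       msm_lag_ns = 20, n_macro = c(2L, 4L),
                       exclude = integer(),
                       its_lags = c(1L, 2L, 3L, 5L), ck_steps = 1:3,
                       ck_boot = 10L,
                       bins = 80L, kT = 0.5962, seed = 1L) {
  if (tica_lag_ns <= 0 || msm_lag_ns <= 0) stop("lags must be positive")
  if (is.null(feature_files) && !inherits(kinetics, "ground_truth_kinetics"))
    stop("either `kinetics` or `feature_files` must be supplied")
  if (n_macro[1] != 2L) stop("the first macrostate count must be 2")
  cfg <- list(condition = condition, kinetics = kinetics,
              feature_files = feature_files,
              n_trajectories = as.integer(n_trajectories),
              n_steps = as.integer(n_steps),
              expand_blocks = isTRUE(expand_blocks),
              tica_lag_ns = tica_lag_ns, n_tica_dims = n_tica_dims,
              cluster_k = as.integer(cluster_k),
              kmeans_restarts = as.integer(kmeans_restarts),
              fit_sample = as.integer(fit_sample),
              msm_lag_ns = msm_lag_ns, n_macro = as.integer(n_macro),
              exclude = as.integer(exclude),
              its_lags = as.integer(its_lags), ck_steps = as.integer(ck_steps),
              ck_boot = as.integer(ck_boot),
              bins = as.integer(bins), kT = kT, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' MD5 hash of a run configuration
#'
#' Embedded in every output so results are traceable to the exact
#' configuration that produced them.
#'
#' @param config a [run_config()].
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(unclass(config)))]), tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full gating-analysis pipeline
#'
#' Executes, per condition: input generation or loading, optional 5-fold
#' symmetry block expansion, tICA with kinetic mapping and single-Gaussian
#' dimension pruning, k-means microstate discretization, reversible MSM
#' estimation with implied-timescale and Chapman-Kolmogorov validation,
#' PCCA+ coarse-graining into two metastable macrostates (and any further
#' requested macrostate counts), stationary populations, mean first-passage
#' times, and the stationary-reweighted free-energy landscape with its
#' barrier height. Identical configuration and seed yield an identical
#' result bundle.
#'
#' @param config a [run_config()].
#' @return an object of class `gating_run`; see [gating_summary()] for the
#'   serializable summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  sub_seeds <- sample.int(2^31 - 2, 2L * config$n_trajectories + 2L)

  trajs <- .stage("input", {
    if (!is.null(config$feature_files)) {
      missing <- config$feature_files[!file.exists(config$feature_files)]
      if (length(missing))
        stop("missing trajectory input: ", paste(missing, collapse = ", "))
      lapply(config$feature_files, read_feature_csv)
    } else {
      kin <- config$kinetics
      starts <- 1L + (seq_len(config$n_trajectories) - 1L) %% nrow(kin$T)
      lapply(seq_len(config$n_trajectories), function(i) {
        s <- sample_markov_chain(kin, config$n_steps, start_state = starts[i],
                                 seed = sub_seeds[i])
        emit_features(s, kin,
                      seed = sub_seeds[config$n_trajectories + i])
      })
    }
  })
  if (length(config$exclude))
    trajs <- trajs[-config$exclude]
  n_input <- length(trajs)
  if (config$expand_blocks)
    trajs <- do.call(c, lapply(trajs, expand_feature_blocks))

  tica_model <- .stage("tica", {
    cov <- estimate_covariances(trajs, lag = config$tica_lag_ns)
    fit_tica(cov, kinetic_map = TRUE)
  })
  projections <- .stage("tica", {
    dims_all <- seq_len(min(tica_model$rank, 10L))
    proj_all <- lapply(trajs, function(x) predict(tica_model, x, dims = dims_all))
    sub <- do.call(rbind, lapply(proj_all, function(p)
      p[round(seq(1, nrow(p), length.out = max(2, min(nrow(p), 2000)))), ,
        drop = FALSE]))
    dims <- select_dimensions(sub)
    if (!is.null(config$n_tica_dims))
      dims <- dims[seq_len(min(config$n_tica_dims, length(dims)))]
    tica_model$retained <- length(dims)
    lapply(proj_all, function(p) p[, dims, drop = FALSE])
  })
  dims_used <- ncol(projections[[1]])

  micro <- .stage("cluster", {
    cluster_microstates(projections, k = config$cluster_k,
                        seed = sub_seeds[2L * config$n_trajectories + 1L],
                        nstart = config$kmeans_restarts,
                        fit_sample = config$fit_sample)
  })

  stride <- attr(trajs[[1]], "stride")
  if (is.null(stride)) stride <- 1
  model <- .stage("msm", {
    markov_model(micro$dtrajs, lag = config$msm_lag_ns, stride_ns = stride,
                 centers = micro$centers)
  })
  its <- .stage("msm", {
    implied_timescales(micro$dtrajs, lags = config$its_lags,
                       stride_ns = stride)
  })

  macro2 <- .stage("macro", suppressWarnings(pcca_macrostates(model, 2L)))
  # identify the open-like macrostate from the first feature (a pore
  # expansion distance in the default generator: larger when open)
  f1 <- unlist(lapply(trajs, function(x) .ft_matrix(x)[, 1]),
               use.names = FALSE)
  s_act <- unlist(model$dtrajs, use.names = FALSE)
  okf <- !is.na(s_act)
  macro_of_frame <- macro2$assignment[s_act[okf]]
  mean_f1 <- vapply(1:2, function(a) mean(f1[okf][macro_of_frame == a]), 0)
  open_idx <- which.max(mean_f1)
  labels2 <- rep("closed", 2)
  labels2[open_idx] <- "open"
  populations2 <- stats::setNames(macro2$populations, labels2)
  mfpt2 <- macro2$mfpt_us
  dimnames(mfpt2) <- list(labels2, labels2)

  ck <- .stage("validation", {
    sets <- split(seq_len(nrow(model$T)), macro2$assignment)
    names(sets) <- labels2
    ck_test(micro$dtrajs, lag = config$msm_lag_ns, stride_ns = stride,
            macro_sets = sets, k_steps = config$ck_steps,
            nboot = config$ck_boot,
            seed = sub_seeds[2L * config$n_trajectories + 2L])
  })

  landscape <- .stage("landscape", {
    free_energy_landscape(do.call(rbind, projections), model,
                          bins = config$bins, kT = config$kT)
  })
  barrier <- tryCatch(
    barrier_height(landscape, macro_of_frame),
    error = function(e) NA_real_)

  macro_extra <- list()
  for (nm in setdiff(config$n_macro, 2L)) {
    macro_extra[[as.character(nm)]] <-
      .stage("macro", suppressWarnings(pcca_macrostates(model, nm)))
  }

  out <- list(config = config, config_hash = hash,
              package_version = as.character(utils::packageVersion("pentagate")),
              n_trajectories_used = n_input,
              n_expanded = length(trajs),
              frames_total = sum(vapply(trajs, nrow, 0L)),
              excluded_trajectories = config$exclude,
              tica = tica_model, tica_dims_used = dims_used,
              microstates_k = micro$k,
              active_states = length(model$active),
              discarded_frames = model$excluded_frames,
              msm = model, implied_timescales = its,
              macro2 = macro2, macro_labels = labels2,
              populations = populations2, mfpt_us = mfpt2,
              ck = ck, landscape = landscape, barrier_kcal_mol = barrier,
              macro_extra = macro_extra)
  class(out) <- "gating_run"
  out
}

#' @export
print.gating_run <- function(x, ...) {
  cat("gating_run:", x$config$condition, "| config", substr(x$config_hash, 1, 8),
      "\n")
  cat("  ", x$n_trajectories_used, "trajectories,", x$frames_total, "frames,",
      x$active_states, "active microstates,", x$tica_dims_used, "tICA dims\n")
  cat("  populations:",
      paste(sprintf("%s = %.3f", names(x$populations), x$populations),
            collapse = ", "), "\n")
  cat("  MFPT closed->open:", signif(x$mfpt_us["closed", "open"], 4),
      "us; open->closed:", signif(x$mfpt_us["open", "closed"], 4), "us\n")
  if (is.finite(x$barrier_kcal_mol))
    cat("  barrier:", signif(x$barrier_kcal_mol, 3), "kcal/mol\n")
  invisible(x)
}

#' Serializable summary of a pipeline run
#'
#' Plain-list digest of a [run_pipeline()] bundle — populations, MFPTs,
#' implied timescales, tICA spectrum, validation and audit counts — with the
#' configuration hash and package version embedded.
#'
#' @param run a `gating_run`.
#' @return a named list suitable for [jsonlite::toJSON()].
#' @export
gating_summary <- function(run) {
  stopifnot(inherits(run, "gating_run"))
  lam <- run$msm$eigenvalues
  its2 <- if (length(lam) > 1 && lam[2] > 0 && lam[2] < 1)
    -run$msm$lag / log(lam[2]) else NA_real_
  list(condition = run$config$condition,
       config_hash = run$config_hash,
       package_version = run$package_version,
       seed = run$config$seed,
       n_trajectories = run$n_trajectories_used,
       n_frames = run$frames_total,
       excluded_trajectories = run$excluded_trajectories,
       discarded_frames = run$discarded_frames,
       tica_eigenvalues = round(utils::head(run$tica$eigenvalues, 5), 10),
       tica_dims_used = run$tica_dims_used,
       microstates_k = run$microstates_k,
       active_states = run$active_states,
       populations = as.list(round(run$populations, 10)),
       mfpt_us = list(closed_to_open = round(run$mfpt_us["closed", "open"], 10),
                      open_to_closed = round(run$mfpt_us["open", "closed"], 10)),
       slowest_implied_timescale_ns = round(its2, 10),
       barrier_kcal_mol = round(run$barrier_kcal_mol, 10))
}

#' Write a run summary as JSON
#'
#' @param run a `gating_run`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_json <- function(run, path) {
  json <- jsonlite::toJSON(gating_summary(run), auto_unbox = TRUE,
                           digits = NA, null = "null", na = "null",
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
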