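#' Per-frame feature matrix with trajectory metadata
#'
#' Thin matrix wrapper recording the frame stride (ns), the condition label,
#' a seed/replicate id, the subunit-rotation index of a symmetry-expanded
#' copy, and the number of homologous feature blocks.
#'
#' @param x numeric frames x features matrix.
#' @param stride physical time between consecutive frames (ns).
#' @param condition free-form condition label.
#' @param seed_id replicate identifier.
#' @param rotation subunit-rotation index in `0:4` for symmetry-expanded
#'   copies.
#' @param n_blocks number of homologous feature blocks (NA if not
#'   block-structured).
#' @return an object of class `feature_trajectory` (a matrix).
#' @export
feature_trajectory <- function(x, stride = 1, condition = "unspecified",
                               seed_id = NA_integer_, rotation = 0L,
                               n_blocks = NA_integer_) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  structure(x, class = c("feature_trajectory", "matrix", "array"),
            stride = stride, condition = condition, seed_id = seed_id,
            rotation = as.integer(rotation), n_blocks = as.integer(n_blocks))
}

#' @export
print.feature_trajectory <- function(x, ...) {
  cat("feature_trajectory:", nrow(x), "frames x", ncol(x), "features,",
      "stride", attr(x, "stride"), "ns, rotation", attr(x, "rotation"), "\n")
  invisible(x)
}

# strip class but keep the bare matrix
.ft_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Declarative interatomic-distance feature specification
#'
#' Each row names a bead pair by within-subunit bead index and a subunit
#' *role* resolved cyclically against a reference subunit: `self` is the
#' reference subunit itself, `principal+1`/`principal+2` the next subunits in
#' the principal (counterclockwise, viewed from the extracellular side)
#' direction, and `complementary-1`/`complementary-2` the preceding ones.
#' Under cyclic arithmetic mod 5 every role resolves to a concrete subunit
#' for any reference subunit.
#'
#' @param bead_a,bead_b within-subunit bead indices.
#' @param role_a,role_b subunit roles (see Details).
#' @return a data frame of class `feature_spec`.
#' @export
feature_spec <- function(bead_a, role_a, bead_b, role_b) {
  roles <- names(.role_offsets)
  role_a <- match.arg(as.character(role_a), roles, several.ok = TRUE)
  role_b <- match.arg(as.character(role_b), roles, several.ok = TRUE)
  df <- data.frame(bead_a = as.integer(bead_a), role_a = role_a,
                   bead_b = as.integer(bead_b), role_b = role_b,
                   stringsAsFactors = FALSE)
  key <- apply(df, 1, function(r) {
    ends <- sort(c(paste(r[["role_a"]], r[["bead_a"]]),
                   paste(r[["role_b"]], r[["bead_b"]])))
    paste(ends, collapse = "|")
  })
  if (anyDuplicated(key)) stop("duplicate feature pairs in spec")
  class(df) <- c("feature_spec", "data.frame")
  df
}

.role_offsets <- c("self" = 0L, "principal+1" = 1L, "principal+2" = 2L,
                   "complementary-1" = -1L, "complementary-2" = -2L)

#' Default feature specification for a toy pentamer
#'
#' Emphasizes transmembrane-domain helix interactions: all within-subunit
#' TMD bead pairs plus each TMD bead paired with its homolog in the two
#' principal-side neighbors.
#'
#' @param structure a [coarse_structure()] used to enumerate TMD beads.
#' @return a [feature_spec()].
#' @export
default_feature_spec <- function(structure) {
  tmd <- sort(unique(structure$atoms$bead[structure$atoms$domain == "TMD"]))
  if (length(tmd) == 0) stop("structure has no TMD beads")
  rows <- list()
  if (length(tmd) > 1) {
    cmb <- utils::combn(tmd, 2)
    for (i in seq_len(ncol(cmb)))
      rows[[length(rows) + 1L]] <- list(cmb[1, i], "self", cmb[2, i], "self")
  }
  for (b in tmd) for (r in c("principal+1", "principal+2"))
    rows[[length(rows) + 1L]] <- list(b, "self", b, r)
  feature_spec(bead_a = vapply(rows, `[[`, 0, 1),
               role_a = vapply(rows, `[[`, "", 2),
               bead_b = vapply(rows, `[[`, 0, 3),
               role_b = vapply(rows, `[[`, "", 4))
}

#' Resolve feature-spec roles against a reference subunit
#'
#' @param spec a [feature_spec()].
#' @param reference_subunit subunit index in `0:4`.
#' @return the spec with concrete `subunit_a`/`subunit_b` columns.
#' @export
resolve_roles <- function(spec, reference_subunit = 0L) {
  r <- as.integer(reference_subunit)
  spec$subunit_a <- (r + .role_offsets[spec$role_a]) %% 5L
  spec$subunit_b <- (r + .role_offsets[spec$role_b]) %% 5L
  spec
}

#' Compute interatomic-distance features for a trajectory
#'
#' Euclidean distances between the resolved bead pairs, one row per frame,
#' in spec order.
#'
#' @param trajectory a [coarse_structure()] or a list of them (frames must
#'   share topology).
#' @param spec a [feature_spec()].
#' @param reference_subunit subunit against which roles are resolved.
#' @param stride frame stride in ns.
#' @return a [feature_trajectory()] with `nrow(spec)` features.
#' @export
compute_distance_features <- function(trajectory, spec, reference_subunit = 0L,
                                      stride = 1) {
  frames <- if (inherits(trajectory, "coarse_structure")) list(trajectory)
            else trajectory
  res <- resolve_roles(spec, reference_subunit)
  idx <- .bead_index(frames[[1]])
  ia <- .lookup_beads(idx, res$subunit_a, res$bead_a)
  ib <- .lookup_beads(idx, res$subunit_b, res$bead_b)
  X <- t(vapply(frames, function(f) {
    d <- f$xyz[ia, , drop = FALSE] - f$xyz[ib, , drop = FALSE]
    sqrt(rowSums(d * d))
  }, numeric(length(ia))))
  if (length(ia) == 1L) X <- matrix(X, ncol = 1L)
  feature_trajectory(X, stride = stride, rotation = as.integer(reference_subunit))
}

#' Symmetry-aware feature expansion of a pentamer trajectory
#'
#' Scores the distances originating from each of the five subunits as an
#' independent trajectory: the same feature spec is resolved against every
#' reference subunit in turn, so each expanded copy describes how one
#' subunit moves in relation to all others. Pooling the five copies makes
#' every downstream statistic invariant under cyclic relabeling of the
#' subunits.
#'
#' @inheritParams compute_distance_features
#' @return a list of 5 [feature_trajectory()]s, rotation indices 0..4, with
#'   identical feature ordering.
#' @export
symmetry_expand <- function(trajectory, spec, stride = 1) {
  frames <- if (inherits(trajectory, "coarse_structure")) list(trajectory)
            else trajectory
  n_sub <- length(unique(frames[[1]]$atoms$subunit))
  if (n_sub != 5L)
    stop("symmetry expansion is defined for pentamers (found ", n_sub,
         " subunits)")
  lapply(0:4, function(r)
    compute_distance_features(frames, spec, reference_subunit = r,
                              stride = stride))
}

#' Cyclic block expansion of a block-structured feature trajectory
#'
#' Feature-space analogue of [symmetry_expand()] for synthetic trajectories
#' whose columns are organized into homologous subunit blocks: copy `r`
#' cyclically rotates the block order by `r`, so pooled estimates are
#' invariant under relabeling of the blocks.
#'
#' @param ft a [feature_trajectory()] whose column count is divisible by
#'   `n_blocks`.
#' @param n_blocks number of homologous blocks (default from the object).
#' @return list of `n_blocks` rotated [feature_trajectory()] copies.
#' @export
expand_feature_blocks <- function(ft, n_blocks = attr(ft, "n_blocks")) {
  n_blocks <- as.integer(n_blocks)
  F <- ncol(ft)
  if (is.na(n_blocks) || F %% n_blocks != 0L)
    stop("feature count is not divisible into blocks")
  b <- F %/% n_blocks
  lapply(seq_len(n_blocks) - 1L, function(r) {
    perm <- as.vector(outer(seq_len(b), ((seq_len(n_blocks) - 1L + r) %% n_blocks) * b, "+"))
    out <- feature_trajectory(.ft_matrix(ft)[, perm, drop = FALSE],
                              stride = attr(ft, "stride"),
                              condition = attr(ft, "condition"),
                              seed_id = attr(ft, "seed_id"),
                              rotation = r, n_blocks = n_blocks)
    out
  })
}

#' Write / read a feature trajectory as CSV
#'
#' Metadata (stride, condition, rotation, block count) is stored in a
#' `# key: value` comment header.
#'
#' @param ft a [feature_trajectory()].
#' @param file path to a CSV file.
#' @return `write_feature_csv` returns `file` invisibly; `read_feature_csv`
#'   returns a [feature_trajectory()].
#' @export
write_feature_csv <- function(ft, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# stride: %s", attr(ft, "stride")), con)
  writeLines(sprintf("# condition: %s", attr(ft, "condition")), con)
  writeLines(sprintf("# rotation: %s", attr(ft, "rotation")), con)
  writeLines(sprintf("# n_blocks: %s", attr(ft, "n_blocks")), con)
  utils::write.table(.ft_matrix(ft), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(file) {
  hdr <- readLines(file, n = 4L)
  val <- function(i) sub("^# [a-z_]+: ", "", hdr[i])
  X <- as.matrix(utils::read.table(file, sep = ",", comment.char = "#"))
  feature_trajectory(X, stride = as.numeric(val(1)), condition = val(2),
                     rotation = as.integer(val(3)),
                     n_blocks = suppressWarnings(as.integer(val(4))))
}
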