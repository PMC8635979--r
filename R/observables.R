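#' Named residue selections for structural gating observables
#'
#' Maps the observable definitions used for gating channels onto concrete
#' bead selections: the upper pore-lining M2 helix, the 9' hydrophobic gate
#' and the proposed intracellular -2' gate, the neighboring-subunit upper-M1
#' helix, the three-bead M1 kink triplet, the beta1/beta10 salt-bridge sites,
#' the upper extracellular domain, the proton-sensor pair, and the reference
#' selection that defines the pore axis. Each selection is a list with
#' `bead` (within-subunit bead ids) and `role` (subunit role, resolved
#' cyclically as in [feature_spec()]).
#'
#' @param ... named selections, each `list(bead = ..., role = ...)`.
#' @return a named list of class `residue_map`.
#' @export
residue_map <- function(...) {
  m <- list(...)
  required <- c("upper_M2", "gate_9prime", "gate_minus2prime", "M1_upper",
                "M1_kink_triplet", "beta1_site", "beta10_site", "ecd_upper",
                "sensor_pair", "pore_axis_reference")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop("residue_map lacks selections: ", paste(missing, collapse = ", "))
  for (nm in names(m)) {
    if (is.null(m[[nm]]$role)) m[[nm]]$role <- "self"
  }
  structure(m, class = "residue_map")
}

#' Default residue map for the toy pentamer
#'
#' Bead conventions of [make_toy_pentamer()] with the default 4-bead
#' subunits: TMD beads 1-2 (bead 1 plays M2/9', bead 2 plays M1/-2') and
#' ECD beads 3-4 (beta1/beta10 and sensor sites).
#'
#' @return a [residue_map()].
#' @export
default_toy_residue_map <- function() {
  residue_map(
    upper_M2 = list(bead = 1L, role = "self"),
    gate_9prime = list(bead = 1L, role = "self"),
    gate_minus2prime = list(bead = 2L, role = "self"),
    M1_upper = list(bead = 2L, role = "complementary-1"),
    M1_kink_triplet = list(bead = c(2L, 1L, 3L), role = "self"),
    beta1_site = list(bead = 3L, role = "self"),
    beta10_site = list(bead = 4L, role = "self"),
    ecd_upper = list(bead = c(3L, 4L), role = "self"),
    sensor_pair = list(principal = list(bead = 3L, role = "self"),
                       complementary = list(bead = 4L, role = "complementary-1"),
                       role = "self"),
    pore_axis_reference = list(bead = NULL, role = "self"))
}

# pore axis through the centroid of the reference selection: the covariance
# eigenvector whose eigenvalue is most separated from the other two (for a
# C5-symmetric ring stack the two in-plane variances are equal and the axial
# one is the odd one out; for an elongated selection the long axis is).
.pore_axis <- function(structure, map) {
  sel <- map$pore_axis_reference
  a <- structure$atoms
  rows <- if (is.null(sel$bead)) seq_len(nrow(a))
          else which(a$bead %in% sel$bead)
  if (length(rows) < 3L) stop("pore axis needs at least 3 reference points")
  X <- structure$xyz[rows, , drop = FALSE]
  ctr <- colMeans(X)
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  v <- e$values
  gaps <- c(abs(v[1] - v[2]) + abs(v[1] - v[3]),
            abs(v[2] - v[1]) + abs(v[2] - v[3]),
            abs(v[3] - v[1]) + abs(v[3] - v[2]))
  if (max(v) - min(v) < 1e-10 * max(max(v), 1))
    stop("degenerate pore axis: isotropic reference selection")
  pick <- which.max(gaps)
  axis <- e$vectors[, pick]
  # orient along +z-ish direction for reproducible azimuth signs
  if (axis[3] < 0 || (axis[3] == 0 && axis[1] < 0)) axis <- -axis
  list(center = ctr, axis = axis)
}

.axis_frame <- function(ax) {
  u <- ax$axis
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(center = ax$center, axis = u, e1 = e1, e2 = e2)
}

.radial_distance <- function(points, ax) {
  d <- sweep(points, 2, ax$center)
  t <- as.vector(d %*% ax$axis)
  perp <- d - outer(t, ax$axis)
  sqrt(rowSums(perp^2))
}

.selection_rows <- function(structure, bead, subunit) {
  idx <- .bead_index(structure)
  .lookup_beads(idx, rep(subunit, length(bead)), bead)
}

.role_subunit <- function(role, reference) {
  (as.integer(reference) + .role_offsets[[role]]) %% 5L
}

#' Radial pore metrics of one frame
#'
#' Perpendicular distance from the per-subunit centroid of each pore
#' selection (upper M2, the 9' gate, the -2' gate) to the pore axis.
#'
#' @param frame a [coarse_structure()].
#' @param map a [residue_map()].
#' @return list with per-subunit vectors `m2_spread`, `r_9prime`,
#'   `r_minus2prime` and their means (suffix `_mean`), Angstrom.
#' @export
radial_pore_metrics <- function(frame, map = default_toy_residue_map()) {
  ax <- .pore_axis(frame, map)
  one <- function(sel) {
    vapply(0:4, function(s) {
      rows <- .selection_rows(frame, sel$bead, .role_subunit(sel$role, s))
      ctr <- colMeans(frame$xyz[rows, , drop = FALSE])
      .radial_distance(matrix(ctr, 1), ax)
    }, 0)
  }
  m2 <- one(map$upper_M2)
  r9 <- one(map$gate_9prime)
  rm2 <- one(map$gate_minus2prime)
  list(m2_spread = m2, r_9prime = r9, r_minus2prime = rm2,
       m2_spread_mean = mean(m2), r_9prime_mean = mean(r9),
       r_minus2prime_mean = mean(rm2))
}

#' Subunit-interface distance metrics of one frame
#'
#' Centroid-centroid distance between the principal upper-M2 and the
#' complementary upper-M1 selections across each subunit interface, the
#' beta1-beta10 expansion distance, and the proton-sensor pair distance,
#' with roles resolved cyclically for each of the five interfaces.
#'
#' @inheritParams radial_pore_metrics
#' @return list with per-interface vectors `m2_m1_distance`,
#'   `beta_expansion`, `sensor_distance` and their means, Angstrom.
#' @export
interface_metrics <- function(frame, map = default_toy_residue_map()) {
  centroid <- function(sel, ref) {
    rows <- .selection_rows(frame, sel$bead, .role_subunit(sel$role, ref))
    colMeans(frame$xyz[rows, , drop = FALSE])
  }
  pairdist <- function(sel_a, sel_b) {
    vapply(0:4, function(s)
      sqrt(sum((centroid(sel_a, s) - centroid(sel_b, s))^2)), 0)
  }
  m2m1 <- pairdist(map$upper_M2, map$M1_upper)
  beta <- pairdist(map$beta1_site, map$beta10_site)
  sensor <- pairdist(map$sensor_pair$principal, map$sensor_pair$complementary)
  list(m2_m1_distance = m2m1, beta_expansion = beta,
       sensor_distance = sensor,
       m2_m1_distance_mean = mean(m2m1), beta_expansion_mean = mean(beta),
       sensor_distance_mean = mean(sensor))
}

#' Helix kink, ECD spread and ECD twist of one frame
#'
#' The M1 kink is the angle at the middle bead of the kink triplet (180
#' degrees = straight helix). ECD spread is the mean radial distance of the
#' per-subunit upper-ECD centroids from the pore axis. ECD twist is the
#' mean signed azimuthal offset between each subunit's ECD and TMD
#' centroids about the pore axis, reported relative to the same quantity in
#' the reference frame (so a rigid +10 degree ECD rotation reads as +10).
#'
#' @param frame,reference_frame [coarse_structure()]s sharing topology.
#' @param map a [residue_map()].
#' @return list with `m1_kink` (per subunit, degrees), `ecd_spread`
#'   (Angstrom), `ecd_twist` (degrees) and their means.
#' @export
conformational_angles <- function(frame, reference_frame,
                                  map = default_toy_residue_map()) {
  kink_one <- function(f, s) {
    sel <- map$M1_kink_triplet
    rows <- .selection_rows(f, sel$bead, .role_subunit(sel$role, s))
    p <- f$xyz[rows, , drop = FALSE]
    v1 <- p[1, ] - p[2, ]
    v2 <- p[3, ] - p[2, ]
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < 1e-12 || n2 < 1e-12) stop("zero-length limb in the kink triplet")
    acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1)) * 180 / pi
  }
  kink <- vapply(0:4, function(s) kink_one(frame, s), 0)
  ax <- .axis_frame(.pore_axis(frame, map))
  ecd_ctr <- function(f, s, dom) {
    a <- f$atoms
    rows <- which(a$subunit == s & a$domain == dom)
    colMeans(f$xyz[rows, , drop = FALSE])
  }
  spread <- vapply(0:4, function(s) {
    sel <- map$ecd_upper
    rows <- .selection_rows(frame, sel$bead, .role_subunit(sel$role, s))
    ctr <- colMeans(frame$xyz[rows, , drop = FALSE])
    .radial_distance(matrix(ctr, 1), ax)
  }, 0)
  azimuth <- function(p, fr) {
    d <- p - fr$center
    atan2(sum(d * fr$e2), sum(d * fr$e1))
  }
  twist_of <- function(f) {
    fr <- .axis_frame(.pore_axis(f, map))
    vapply(0:4, function(s) {
      a_e <- azimuth(ecd_ctr(f, s, "ECD"), fr)
      a_t <- azimuth(ecd_ctr(f, s, "TMD"), fr)
      d <- (a_e - a_t) * 180 / pi
      ((d + 180) %% 360) - 180
    }, 0)
  }
  tw <- twist_of(frame) - twist_of(reference_frame)
  tw <- ((tw + 180) %% 360) - 180
  list(m1_kink = kink, ecd_spread = spread, ecd_twist = tw,
       m1_kink_mean = mean(kink), ecd_spread_mean = mean(spread),
       ecd_twist_mean = mean(tw))
}

#' Count pore waters inside an axis-aligned cylinder
#'
#' Waters whose perpendicular distance to the pore axis is at most `radius`
#' and whose axial coordinate lies within `z_bounds` (both boundaries
#' closed) are counted; the frame is hydrated when the count exceeds the
#' threshold (default 20 waters).
#'
#' @param frame a [coarse_structure()] defining the pore axis.
#' @param water_coordinates n x 3 matrix of water oxygen positions, same
#'   frame of reference.
#' @param radius cylinder radius (Angstrom, default 5).
#' @param z_bounds axial bounds relative to the axis centroid (default: the
#'   axial span of the TMD beads).
#' @param threshold hydration threshold (count must exceed it).
#' @param map a [residue_map()].
#' @return list with `n_pore_waters` and logical `hydrated`.
#' @export
pore_hydration <- function(frame, water_coordinates, radius = 5,
                           z_bounds = NULL, threshold = 20L,
                           map = default_toy_residue_map()) {
  ax <- .pore_axis(frame, map)
  if (is.null(z_bounds)) {
    tmd <- frame$xyz[frame$atoms$domain == "TMD", , drop = FALSE]
    t <- as.vector(sweep(tmd, 2, ax$center) %*% ax$axis)
    z_bounds <- range(t)
  }
  if (z_bounds[1] > z_bounds[2]) stop("cylinder z bounds are inverted")
  W <- as.matrix(water_coordinates)
  if (nrow(W) == 0L) return(list(n_pore_waters = 0L, hydrated = FALSE))
  d <- sweep(W, 2, ax$center)
  t <- as.vector(d %*% ax$axis)
  perp <- sqrt(rowSums((d - outer(t, ax$axis))^2))
  n <- sum(perp <= radius & t >= z_bounds[1] & t <= z_bounds[2])
  list(n_pore_waters = n, hydrated = n > threshold)
}

#' Pairwise subunit-symmetry RMSD of one frame
#'
#' For every pair of subunits, the homologous atoms (same within-subunit
#' bead ids) are optimally superposed pair-by-pair (Kabsch) and the
#' remaining RMSD reported — the per-pair superposition isolates internal
#' conformational asymmetry from the rigid placement of the subunits around
#' the ring. A pentamer has exactly 5 neighboring pairs (subunit offset
#' 1) and 5 opposing pairs (offset 2).
#'
#' @param frame a [coarse_structure()].
#' @param atom_selection bead ids to compare (default: all beads of the
#'   chosen domain).
#' @param domain `"all"`, `"TMD"` or `"ECD"`.
#' @return data frame with columns `i`, `j`, `pair_class`
#'   (`"neighbor"`/`"opposing"`) and `rmsd` (Angstrom).
#' @export
pairwise_symmetry_rmsd <- function(frame, atom_selection = NULL,
                                   domain = c("all", "TMD", "ECD")) {
  domain <- match.arg(domain)
  a <- frame$atoms
  rows_for <- function(s) {
    r <- which(a$subunit == s &
               (domain == "all" | a$domain == domain) &
               (if (is.null(atom_selection)) TRUE else a$bead %in% atom_selection))
    r[order(a$bead[r])]
  }
  sel <- lapply(0:4, rows_for)
  lens <- vapply(sel, length, 0L)
  if (length(unique(lens)) != 1L)
    stop("unequal homologous atom counts across subunits")
  if (lens[1] == 0L) stop("empty atom selection")
  pairs <- list()
  for (i in 0:4) for (j in 0:4) {
    if (j <= i) next
    off <- min((j - i) %% 5L, (i - j) %% 5L)
    pairs[[length(pairs) + 1L]] <- data.frame(
      i = i, j = j,
      pair_class = if (off == 1L) "neighbor" else "opposing",
      rmsd = kabsch_rmsd(frame$xyz[sel[[i + 1L]], , drop = FALSE],
                         frame$xyz[sel[[j + 1L]], , drop = FALSE]))
  }
  do.call(rbind, pairs)
}

#' Per-frame table of structural gating observables
#'
#' Evaluates all structural observables — radial pore metrics, interface
#' distances, conformational angles, optional pore hydration, and pairwise
#' symmetry RMSD summaries per pair class and domain — for every frame of a
#' trajectory.
#'
#' @param frames list of [coarse_structure()]s (or a single one).
#' @param map a [residue_map()].
#' @param reference_frame reference for the ECD twist (default: the first
#'   frame).
#' @param waters optional list of per-frame water coordinate matrices.
#' @param hydration_threshold pore-water count above which a frame counts
#'   as hydrated.
#' @return a data frame with one row per frame.
#' @export
observable_table <- function(frames, map = default_toy_residue_map(),
                             reference_frame = NULL, waters = NULL,
                             hydration_threshold = 20L) {
  if (inherits(frames, "coarse_structure")) frames <- list(frames)
  if (is.null(reference_frame)) reference_frame <- frames[[1]]
  rows <- lapply(seq_along(frames), function(q) {
    f <- frames[[q]]
    rp <- radial_pore_metrics(f, map)
    im <- interface_metrics(f, map)
    ca <- conformational_angles(f, reference_frame, map)
    sym_all <- pairwise_symmetry_rmsd(f, domain = "all")
    sym_tmd <- pairwise_symmetry_rmsd(f, domain = "TMD")
    sym_ecd <- pairwise_symmetry_rmsd(f, domain = "ECD")
    msd <- function(df, cls) mean(df$rmsd[df$pair_class == cls])
    out <- data.frame(
      frame = q,
      m2_spread = rp$m2_spread_mean,
      r_9prime = rp$r_9prime_mean,
      r_minus2prime = rp$r_minus2prime_mean,
      m2_m1_distance = im$m2_m1_distance_mean,
      beta_expansion = im$beta_expansion_mean,
      sensor_distance = im$sensor_distance_mean,
      m1_kink = ca$m1_kink_mean,
      ecd_spread = ca$ecd_spread_mean,
      ecd_twist = ca$ecd_twist_mean,
      sym_neighbor = msd(sym_all, "neighbor"),
      sym_opposing = msd(sym_all, "opposing"),
      sym_neighbor_tmd = msd(sym_tmd, "neighbor"),
      sym_opposing_tmd = msd(sym_tmd, "opposing"),
      sym_neighbor_ecd = msd(sym_ecd, "neighbor"),
      sym_opposing_ecd = msd(sym_ecd, "opposing"))
    if (!is.null(waters)) {
      ph <- pore_hydration(f, waters[[q]], threshold = hydration_threshold,
                           map = map)
      out$n_pore_waters <- ph$n_pore_waters
      out$hydrated <- ph$hydrated
    }
    out
  })
  do.call(rbind, rows)
}
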