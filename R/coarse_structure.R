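#' Labeled coarse-grained channel structure
#'
#' A `coarse_structure` holds one bead (typically the C-alpha atom) per
#' residue of a homopentameric channel, labeled by subunit (0..4), domain
#' (`"TMD"` or `"ECD"`) and a within-subunit bead index. It is the geometric
#' substrate for pathway seeding, featurization, structural observables and
#' subunit-symmetry analysis.
#'
#' @param xyz numeric matrix with one row per bead and columns x, y, z
#'   (Angstrom).
#' @param subunit integer vector of subunit indices in `0:4`, one per bead.
#' @param domain character vector of domain labels, one per bead.
#' @param bead integer vector of within-subunit bead (residue) indices.
#' @return An object of class `coarse_structure` with components `xyz`
#'   (coordinate matrix) and `atoms` (data frame of labels).
#' @export
coarse_structure <- function(xyz, subunit, domain, bead) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("`xyz` must have three columns (x, y, z)")
  n <- nrow(xyz)
  subunit <- as.integer(subunit)
  bead <- as.integer(bead)
  domain <- as.character(domain)
  if (length(subunit) == 1L) subunit <- rep(subunit, n)
  if (length(domain) == 1L) domain <- rep(domain, n)
  if (length(bead) == 1L) bead <- rep(bead, n)
  if (length(subunit) != n || length(domain) != n || length(bead) != n)
    stop("labels must have one entry per bead")
  if (anyNA(subunit)) stop("subunit labels must not contain NA")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(
    list(xyz = xyz,
         atoms = data.frame(bead = bead, subunit = subunit, domain = domain,
                            stringsAsFactors = FALSE)),
    class = "coarse_structure")
}

#' @export
print.coarse_structure <- function(x, ...) {
  cat("coarse_structure:", nrow(x$xyz), "beads,",
      length(unique(x$atoms$subunit)), "subunits,",
      "domains:", paste(unique(x$atoms$domain), collapse = "/"), "\n")
  invisible(x)
}

#' Extract or replace coordinates of a coarse structure
#'
#' @param x a [coarse_structure()].
#' @return `coords()` returns the n x 3 coordinate matrix.
#' @export
coords <- function(x) UseMethod("coords")

#' @export
coords.coarse_structure <- function(x) x$xyz

#' @rdname coords
#' @param value replacement n x 3 coordinate matrix.
#' @export
`coords<-` <- function(x, value) {
  value <- as.matrix(value)
  stopifnot(identical(dim(value), dim(x$xyz)))
  x$xyz[] <- value
  x
}

#' Rotate a structure about the z axis
#'
#' Utility used by the synthetic generators and symmetry checks.
#'
#' @param x a [coarse_structure()] or an n x 3 coordinate matrix.
#' @param angle_deg rotation angle in degrees (counterclockwise viewed from
#'   +z, i.e. from the extracellular side in the package convention).
#' @return the rotated object, same class as the input.
#' @export
rotate_z <- function(x, angle_deg) {
  th <- angle_deg * pi / 180
  # transpose of the standard rotation matrix: coordinates are row vectors,
  # so x %*% R rotates counterclockwise viewed from +z
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  if (inherits(x, "coarse_structure")) {
    coords(x) <- x$xyz %*% R
    x
  } else {
    as.matrix(x) %*% R
  }
}

#' Cyclically relabel the subunits of a pentamer
#'
#' Maps subunit `i` to `(i + shift) mod 5` without moving any coordinates.
#' Used to verify that downstream statistics are invariant under the choice
#' of which subunit is called "0".
#'
#' @param x a [coarse_structure()].
#' @param shift integer relabeling offset.
#' @return a relabeled `coarse_structure`.
#' @export
cycle_subunits <- function(x, shift = 1L) {
  x$atoms$subunit <- (x$atoms$subunit + as.integer(shift)) %% 5L
  x
}

# row indices of beads for (subunit, bead-id) lookup; k = 5 subunits assumed
.bead_index <- function(structure) {
  a <- structure$atoms
  key <- paste(a$subunit, a$bead, sep = ":")
  idx <- seq_len(nrow(a))
  names(idx) <- key
  idx
}

.lookup_beads <- function(index, subunit, bead) {
  key <- paste(subunit, bead, sep = ":")
  out <- index[key]
  if (anyNA(out))
    stop("selection does not resolve: ", paste(key[is.na(out)], collapse = ", "))
  unname(out)
}

#' Write a coarse structure to a PDB file
#'
#' Beads are written as CA atoms; subunits map to chains A-E and the
#' within-subunit bead index to the residue number.
#'
#' @param x a [coarse_structure()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure_pdb <- function(x, file) {
  a <- x$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(x$xyz)),
                   type = rep("ATOM", nrow(x$xyz)),
                   resno = a$bead,
                   resid = ifelse(a$domain == "TMD", "TMD", "ECD"),
                   elety = rep("CA", nrow(x$xyz)),
                   chain = LETTERS[a$subunit + 1L])
  invisible(file)
}

#' Read the C-alpha trace of a PDB file as a coarse structure
#'
#' Extracts CA atoms by atom name; chains map to subunits 0..4 in order of
#' appearance. Domain labels are taken from the residue name when it is
#' `TMD`/`ECD` (as written by [write_structure_pdb()]) and default to `"TMD"`
#' otherwise.
#'
#' @param file path to a PDB file.
#' @return a [coarse_structure()].
#' @export
read_calpha_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  at <- pdb$atom[sel$atom, ]
  chains <- unique(at$chain)
  dom <- ifelse(at$resid %in% c("TMD", "ECD"), at$resid, "TMD")
  coarse_structure(xyz = as.matrix(at[, c("x", "y", "z")]),
                   subunit = match(at$chain, chains) - 1L,
                   domain = dom,
                   bead = at$resno)
}

# Kabsch optimal superposition; returns the minimal RMSD between two
# coordinate sets after removing the rigid-body transform.
kabsch_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(identical(dim(P), dim(Q)))
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  diffs <- Qc - Pc %*% t(R)
  sqrt(mean(rowSums(diffs^2)))
}

#' Optimal-superposition RMSD between two coordinate sets
#'
#' Kabsch/SVD rigid superposition (rotation + translation, no reflection)
#' followed by the root-mean-square deviation over beads.
#'
#' @param a,b [coarse_structure()]s or n x 3 coordinate matrices with
#'   matching row order.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(a, b) {
  A <- if (inherits(a, "coarse_structure")) a$xyz else a
  B <- if (inherits(b, "coarse_structure")) b$xyz else b
  kabsch_rmsd(A, B)
}
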