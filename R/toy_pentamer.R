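#' Specification of a toy pentamer geometry
#'
#' Describes an idealized C5-symmetric two-domain pentamer: each subunit
#' carries `beads_per_subunit` beads distributed evenly over ring layers,
#' one ring per domain, with a per-layer circumradius and z offset. The toy
#' closed and open conformations differ only in the stated radii, mimicking
#' the radial pore expansion that distinguishes closed- and open-channel
#' structures of pentameric ligand-gated ion channels.
#'
#' @param beads_per_subunit total beads per subunit; must be divisible by the
#'   number of layers.
#' @param radii named numeric vector of per-layer ring circumradii (Angstrom);
#'   names give the domain labels (default one TMD and one ECD layer).
#' @param layer_heights z offset of each layer (Angstrom), same length and
#'   order as `radii`.
#' @param conformation label, `"closed"` or `"open"`.
#' @return an object of class `toy_pentamer_spec`.
#' @seealso [make_toy_pentamer()], [closed_pentamer_spec()],
#'   [open_pentamer_spec()]
#' @export
toy_pentamer_spec <- function(beads_per_subunit = 4L,
                              radii = c(TMD = 10, ECD = 11),
                              layer_heights = c(TMD = 0, ECD = 10),
                              conformation = c("closed", "open")) {
  conformation <- match.arg(conformation)
  beads_per_subunit <- as.integer(beads_per_subunit)
  if (length(radii) != length(layer_heights))
    stop("invalid spec: `radii` and `layer_heights` lengths differ")
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("invalid spec: radii must be positive")
  if (beads_per_subunit < 1L)
    stop("invalid spec: beads_per_subunit must be >= 1")
  if (beads_per_subunit %% length(radii) != 0L)
    stop("invalid spec: beads_per_subunit must be divisible by the number of layers")
  if (is.null(names(radii))) names(radii) <- paste0("L", seq_along(radii))
  structure(list(beads_per_subunit = beads_per_subunit, radii = radii,
                 layer_heights = layer_heights, conformation = conformation),
            class = "toy_pentamer_spec")
}

#' @rdname toy_pentamer_spec
#' @param tmd_radius circumradius of the TMD ring (Angstrom).
#' @param ... passed on to [toy_pentamer_spec()].
#' @export
closed_pentamer_spec <- function(tmd_radius = 10, ...) {
  toy_pentamer_spec(radii = c(TMD = tmd_radius, ECD = 11),
                    conformation = "closed", ...)
}

#' @rdname toy_pentamer_spec
#' @export
open_pentamer_spec <- function(tmd_radius = 12, ...) {
  toy_pentamer_spec(radii = c(TMD = tmd_radius, ECD = 11),
                    conformation = "open", ...)
}

#' Build a C5-symmetric toy pentamer structure
#'
#' Generates labeled bead coordinates from a [toy_pentamer_spec()]. Bead `b`
#' (0-based) of layer `l` in subunit `s` sits at azimuth
#' `2*pi*s/5 + b * 2*pi/(5*beads_per_layer)`, so rotating the structure by 72
#' degrees about z maps subunit `i` exactly onto subunit `i+1`.
#'
#' @param spec a [toy_pentamer_spec()].
#' @return a [coarse_structure()] with `5 * beads_per_subunit` beads.
#' @examples
#' ring <- make_toy_pentamer(toy_pentamer_spec(1, radii = c(TMD = 10),
#'                                             layer_heights = c(TMD = 0)))
#' nrow(coords(ring))  # 5 points on a regular pentagon
#' @export
make_toy_pentamer <- function(spec = closed_pentamer_spec()) {
  stopifnot(inherits(spec, "toy_pentamer_spec"))
  n_layers <- length(spec$radii)
  bpl <- spec$beads_per_subunit %/% n_layers
  rows <- vector("list", 5L * spec$beads_per_subunit)
  i <- 0L
  for (s in 0:4) {
    for (l in seq_len(n_layers)) {
      for (b in seq_len(bpl) - 1L) {
        th <- 2 * pi * s / 5 + b * 2 * pi / (5 * bpl)
        i <- i + 1L
        rows[[i]] <- c(spec$radii[l] * cos(th), spec$radii[l] * sin(th),
                       spec$layer_heights[l], s, (l - 1L) * bpl + b + 1L, l)
      }
    }
  }
  m <- do.call(rbind, rows)
  coarse_structure(xyz = m[, 1:3],
                   subunit = m[, 4],
                   domain = names(spec$radii)[m[, 6]],
                   bead = m[, 5])
}
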