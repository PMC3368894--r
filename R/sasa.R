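#' Deterministic quasi-uniform points on the unit sphere
#'
#' Fibonacci (golden-spiral) lattice; the same point set is reused for every
#' atom so SASA is deterministic for a fixed resolution.
#'
#' @param n number of points (default 960).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n = 960) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe of radius `probe` (default 1.4 Angstrom, a water molecule)
#' over the van der Waals surface.  For each atom, quadrature points on the
#' probe-expanded sphere are tested for occlusion by the probe-expanded
#' spheres of all neighbouring atoms; the accessible fraction times the
#' sphere area gives the atom's SASA.  An isolated atom of radius rho gets
#' exactly 4*pi*(rho+probe)^2; a fully enclosed atom gets 0.
#'
#' @param structure a typed `ppi_structure` (radii required).
#' @param probe probe radius in Angstrom (> 0).
#' @param points quadrature points per atom (>= 1; default 960).
#' @param orient optional 3x3 rotation applied to the quadrature sphere, so
#'   that rotating a structure together with the point set reproduces the
#'   original areas to floating-point accuracy.
#' @return numeric vector of per-atom SASA values (Angstrom^2).
#' @export
compute_sasa <- function(structure, probe = 1.4, points = 960, orient = NULL) {
  stopifnot(probe > 0, points >= 1)
  a <- structure$atoms
  if (nrow(a) == 0L) return(numeric(0))
  if (anyNA(a$radius))
    stop("untyped atoms present; run assign_atom_types() first")
  P <- sphere_points(points)
  if (!is.null(orient)) P <- P %*% t(orient)
  xyz <- coords(structure)
  rr <- a$radius + probe
  n <- nrow(a)
  out <- numeric(n)
  # neighbour prefilter: atoms can only occlude within the sum of expanded radii
  maxrr <- max(rr)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rr[i] + rr)^2 & seq_len(n) != i)
    if (!length(nb)) { out[i] <- 4 * pi * rr[i]^2; next }
    pts <- P * rr[i]
    pts[, 1] <- pts[, 1] + xyz[i, 1]
    pts[, 2] <- pts[, 2] + xyz[i, 2]
    pts[, 3] <- pts[, 3] + xyz[i, 3]
    free <- rep(TRUE, points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
        (pts[free, 3] - xyz[j, 3])^2
      free[free] <- dj2 > rr[j]^2
    }
    out[i] <- 4 * pi * rr[i]^2 * sum(free) / points
  }
  out
}

#' Annotate a structure with unbound-state SASA and the surface flag
#'
#' @param structure a typed `ppi_structure`.
#' @param probe probe radius (Angstrom).
#' @param points quadrature points per atom.
#' @return the structure with `sasa_u` and `is_surface` (SASA_u > 0) filled.
#' @export
add_sasa <- function(structure, probe = 1.4, points = 960) {
  structure$atoms$sasa_u <- compute_sasa(structure, probe, points)
  structure$atoms$is_surface <- structure$atoms$sasa_u > 0
  structure
}
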