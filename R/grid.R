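# Axis-aligned (optionally re-oriented) cubic grids around a query protein.
#
# Cell i (1-based per axis) is centred at origin + R %*% ((i - 0.5) * spacing)
# where R is the grid orientation (identity by default).  The optional
# orientation lets a grid rotate rigidly with a structure, which is how the
# rigid-motion invariance of density maps and features is expressed exactly.

#' Grid geometry specification
#'
#' @param origin global position of the grid-frame origin (corner).
#' @param spacing cell edge in Angstrom.
#' @param dims integer cell counts per axis.
#' @param orientation 3x3 rotation giving the grid axes (default identity).
#' @return a `ppi_grid` object.
#' @export
grid_spec <- function(origin, spacing, dims, orientation = diag(3)) {
  stopifnot(length(origin) == 3, spacing > 0, length(dims) == 3,
            all(dims >= 1))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = as.integer(dims), orientation = orientation),
            class = "ppi_grid")
}

#' Grid covering a structure with a margin
#'
#' The box extends `margin` Angstrom (default 10) beyond the bounding box of
#' the atoms on every side, so that the 5 A feature sphere around any
#' surface atom stays inside the grid.
#'
#' @param structure a `ppi_structure`.
#' @param spacing cell edge (default 1.0 A).
#' @param margin margin beyond the atom bounding box (default 10.0 A; covers both the 5 A density sphere and the 10 A patch/geometry sphere).
#' @param orientation optional grid orientation.
#' @return a `ppi_grid`.
#' @export
grid_for_structure <- function(structure, spacing = 1.0, margin = 10.0,
                               orientation = diag(3)) {
  q <- coords(structure) %*% orientation   # coordinates on the grid axes
  lo <- apply(q, 2, min) - margin
  hi <- apply(q, 2, max) + margin
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  grid_spec(origin = as.numeric(orientation %*% lo), spacing = spacing,
            dims = dims, orientation = orientation)
}

# points (m x 3, global) -> continuous grid-frame coordinates in Angstrom
grid_frame_coords <- function(grid, pts) {
  pts <- matrix(pts, ncol = 3)
  # q = t(R) %*% (p - origin), rowwise
  (pts %*% grid$orientation) -
    matrix(as.numeric(crossprod(grid$orientation, grid$origin)),
           nrow(pts), 3, byrow = TRUE)
}

# linear indices (and centre coordinates) of cells whose centres lie within
# `radius` of global point `center`; errors when the sphere exits the grid
# unless clip = TRUE.
cells_in_sphere <- function(grid, center, radius, clip = FALSE) {
  q <- as.numeric(grid_frame_coords(grid, center))
  sp <- grid$spacing
  # cell centres sit at (i - 0.5) * sp: the window covers exactly the cells
  # whose centre can lie within `radius` on each axis
  lo <- as.integer(ceiling((q - radius) / sp + 0.5 - 1e-9))
  hi <- as.integer(floor((q + radius) / sp + 0.5 + 1e-9))
  if (!clip && (any(lo < 1L) || any(hi > grid$dims)))
    stop("sphere of radius ", radius,
         " exits the grid; increase the grid margin")
  lo <- pmax(lo, 1L); hi <- pmin(hi, grid$dims)
  if (any(hi < lo)) return(integer(0))
  ii <- seq.int(lo[1], hi[1]); jj <- seq.int(lo[2], hi[2])
  kk <- seq.int(lo[3], hi[3])
  g <- expand.grid(i = ii, j = jj, k = kk)
  cx <- (g$i - 0.5) * sp; cy <- (g$j - 0.5) * sp; cz <- (g$k - 0.5) * sp
  keep <- (cx - q[1])^2 + (cy - q[2])^2 + (cz - q[3])^2 <= radius^2
  g <- g[keep, , drop = FALSE]
  (g$k - 1L) * grid$dims[1] * grid$dims[2] + (g$j - 1L) * grid$dims[1] + g$i
}

#' Van der Waals occupancy grid
#'
#' A cell is occupied iff its centre lies within the van der Waals radius
#' of some atom.
#'
#' @param structure a typed `ppi_structure`.
#' @param grid a `ppi_grid` covering the structure.
#' @return logical array of dimension `grid$dims`.
#' @export
compute_occupancy <- function(structure, grid) {
  a <- structure$atoms
  if (anyNA(a$radius)) stop("untyped atoms; run assign_atom_types() first")
  q <- grid_frame_coords(grid, coords(structure))
  if (nrow(q) && (any(apply(q, 2, min) < 0) ||
                  any(apply(q, 2, max) > grid$dims * grid$spacing)))
    stop("grid does not cover the structure")
  occ <- array(FALSE, grid$dims)
  for (i in seq_len(nrow(a))) {
    idx <- cells_in_sphere(grid, coords(structure)[i, ], a$radius[i],
                           clip = TRUE)
    occ[idx] <- TRUE
  }
  occ
}
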