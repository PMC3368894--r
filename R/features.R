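# The 32 physicochemical-complementarity attributes of a surface atom:
#   j = 1..31  distance-weighted patch aggregates of local density sums of
#              the 31 probability density maps,
#   j = 32     local surface geometry (unoccupied-space fraction).

#' Local density sum around one atom
#'
#' Sums the density map of interacting type j over all grid cells whose
#' centres lie within `radius` (default 5 A) of the atom centre.
#'
#' @param atom_xyz numeric length-3 atom position.
#' @param map 3D array of one density map (same dims as `grid`).
#' @param grid the `ppi_grid`.
#' @param radius sphere radius in Angstrom.
#' @return scalar S >= 0.
#' @export
sum_local_density <- function(atom_xyz, map, grid, radius = 5.0) {
  idx <- cells_in_sphere(grid, atom_xyz, radius)
  sum(map[idx])
}

#' Distance-weighted patch aggregation of density sums
#'
#' A(i, j) is the weighted average of S(k, j) over the surface atoms k
#' within `radius` (default 10 A) of atom i, atom i itself included at
#' distance 0.  The default taper is linear, w(d) = 1 - d / radius, and
#' weights are normalized so the aggregate is a weighted mean.
#'
#' @param S matrix (atoms x attributes) of local density sums.
#' @param xyz coordinate matrix of the same atoms.
#' @param radius patch radius in Angstrom.
#' @param taper weight function of distance (vectorised).
#' @return matrix of the same shape: A(i, j).
#' @export
aggregate_patch <- function(S, xyz, radius = 10.0,
                            taper = function(d) 1 - d / radius) {
  n <- nrow(S)
  if (n == 0L) return(S)
  A <- S
  d <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n)) {
    nb <- which(d[i, ] <= radius)
    w <- taper(d[i, nb])
    if (sum(w) <= 0) stop("no positive patch weights for atom ", i)
    A[i, ] <- colSums(S[nb, , drop = FALSE] * w) / sum(w)
  }
  A
}

#' Surface geometry attribute
#'
#' The fraction of grid cells whose centres lie in the `radius` (default
#' 10 A) sphere around the atom and are not occupied by the protein van der
#' Waals volume.  Flat or convex local surfaces score high, concave
#' pockets low.
#'
#' @param atom_xyz atom position.
#' @param occupancy logical occupancy array from [compute_occupancy()].
#' @param grid the `ppi_grid`.
#' @param radius sphere radius in Angstrom.
#' @return scalar in \[0, 1\].
#' @export
geometry_feature <- function(atom_xyz, occupancy, grid, radius = 10.0) {
  idx <- cells_in_sphere(grid, atom_xyz, radius)
  if (!length(idx)) return(NA_real_)
  1 - sum(occupancy[idx]) / length(idx)
}

#' Raw 32-attribute matrix for the predictable atoms of one protein
#'
#' @param structure typed structure with SASA and `is_predictable` set.
#' @param pdms result of [project_pdms()] on this structure.
#' @param occupancy occupancy array on the same grid.
#' @param radius_density Eq-style local density radius (default 5 A).
#' @param radius_patch patch aggregation radius (default 10 A).
#' @param taper patch weight function of distance (see [aggregate_patch()]).
#' @return list with `atoms` (identity data.frame of the predictable
#'   atoms), `A` (matrix n x 32), plus the per-atom density sums `S` and
#'   coordinates `xyz` for re-aggregation and diagnostics.
#' @export
encode_features <- function(structure, pdms, occupancy,
                            radius_density = 5.0, radius_patch = 10.0,
                            taper = function(d) 1 - d / radius_patch) {
  a <- structure$atoms
  sel <- which(isTRUE_vec(a$is_predictable))
  grid <- pdms$grid
  n <- length(sel)
  S <- matrix(0, n, 31)
  xyz <- coords(structure)[sel, , drop = FALSE]
  nxyz <- prod(grid$dims)
  flat <- matrix(pdms$values, nrow = nxyz, ncol = 31)
  for (k in seq_len(n)) {
    idx <- cells_in_sphere(grid, xyz[k, ], radius_density)
    S[k, ] <- colSums(flat[idx, , drop = FALSE])
  }
  A <- cbind(aggregate_patch(S, xyz, radius_patch, taper),
             vapply(seq_len(n), function(k)
               geometry_feature(xyz[k, ], occupancy, grid, radius_patch),
               numeric(1)))
  colnames(A) <- c(paste0("pdm", 1:31), "geometry")
  list(atoms = a[sel, c("chain", "resno", "resname", "atom", "type",
                        intersect("dsasa", names(a)),
                        intersect("is_ppi", names(a)))],
       A = A, S = S, xyz = xyz)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Patch taper functions by name
#'
#' The distance-weight function of the patch aggregation is a
#' reconstruction (the published form is unavailable); three tapers are
#' provided: `"linear"` 1 - d/R, `"quadratic"` (1 - d/R)^2, and
#' `"exponential"` exp(-3 d / R), all reaching (near) zero at the patch
#' radius R.
#'
#' @param name taper name.
#' @param radius patch radius R in Angstrom.
#' @return a vectorised function of distance.
#' @export
taper_function <- function(name = c("linear", "quadratic", "exponential"),
                           radius = 10.0) {
  switch(match.arg(name),
         linear = function(d) 1 - d / radius,
         quadratic = function(d) (1 - d / radius)^2,
         exponential = function(d) exp(-3 * d / radius))
}

#' Dataset-level normalization constants
#'
#' For each attribute j, M_max(j) is the median over proteins of the
#' per-protein maximum of A(., j), and M_min(j) the median of the
#' per-protein minima.
#'
#' @param A_list list of per-protein raw attribute matrices.
#' @return list with numeric vectors `M_min` and `M_max` (length 32).
#' @export
fit_normalization <- function(A_list) {
  A_list <- A_list[vapply(A_list, function(m) nrow(m) > 0, logical(1))]
  if (!length(A_list)) stop("no proteins with attributes to normalize")
  maxs <- t(vapply(A_list, function(m) apply(m, 2, max), numeric(32)))
  mins <- t(vapply(A_list, function(m) apply(m, 2, min), numeric(32)))
  list(M_min = apply(mins, 2, stats::median),
       M_max = apply(maxs, 2, stats::median))
}

#' Scale raw attributes to \[0, 1\]
#'
#' Clamp-then-linear: a = 1 above M_max, 0 below M_min, otherwise
#' (A - M_min) / (M_max - M_min).  When M_min = M_max for an attribute,
#' values at the point map to 0.5 and the clamps apply elsewhere.
#'
#' @param A raw attribute matrix (n x 32).
#' @param constants from [fit_normalization()].
#' @return matrix of scaled attributes a(i, j) in \[0, 1\].
#' @export
scale_feature <- function(A, constants) {
  A <- rbind(A)  # tolerate a single-row vector
  lo <- constants$M_min
  hi <- constants$M_max
  out <- A
  for (j in seq_len(ncol(A))) {
    if (hi[j] > lo[j]) {
      out[, j] <- pmin(1, pmax(0, (A[, j] - lo[j]) / (hi[j] - lo[j])))
    } else {
      out[, j] <- ifelse(A[, j] > hi[j], 1, ifelse(A[, j] < lo[j], 0, 0.5))
    }
  }
  out
}

#' Write normalization constants as JSON
#' @param constants from [fit_normalization()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_normalization <- function(constants, file) {
  jsonlite::write_json(constants, file, auto_unbox = FALSE, digits = NA)
  invisible(file)
}

#' Read normalization constants written by [write_normalization()]
#' @param file path.
#' @return list with `M_min`, `M_max`.
#' @export
read_normalization <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  list(M_min = as.numeric(x$M_min), M_max = as.numeric(x$M_max))
}
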