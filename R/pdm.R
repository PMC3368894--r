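# Projection of the knowledge base onto a global grid around a query
# protein, yielding one probability density map (PDM) per interacting atom
# type j = 1..31.

# splat of point masses: returns linear indices (into an nx*ny*nz*nj array)
# and weights, deferring the actual accumulation so the large value array
# is touched once per projection.  `u` are continuous grid-frame
# coordinates in Angstrom, `jj` the map index.
splat_trilinear <- function(grid, u, jj, mass) {
  sp <- grid$spacing
  w <- u / sp + 0.5              # cell centres sit at integer w
  b <- floor(w)
  f <- w - b
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  nxyz <- nx * ny * nz
  lin <- integer(0); wt <- numeric(0)
  for (corner in 0:7) {
    ox <- corner %% 2L; oy <- (corner %/% 2L) %% 2L; oz <- corner %/% 4L
    ci <- b[, 1] + ox; cj <- b[, 2] + oy; ck <- b[, 3] + oz
    ww <- mass *
      (if (ox == 1L) f[, 1] else 1 - f[, 1]) *
      (if (oy == 1L) f[, 2] else 1 - f[, 2]) *
      (if (oz == 1L) f[, 3] else 1 - f[, 3])
    ok <- ci >= 1L & ci <= nx & cj >= 1L & cj <= ny & ck >= 1L & ck <= nz &
      ww > 0
    if (!any(ok)) next
    lin <- c(lin, (jj[ok] - 1L) * nxyz + (ck[ok] - 1L) * nx * ny +
               (cj[ok] - 1L) * nx + ci[ok])
    wt <- c(wt, ww[ok])
  }
  list(lin = lin, wt = wt)
}

splat_nearest <- function(grid, u, jj, mass) {
  sp <- grid$spacing
  idx3 <- floor(u / sp) + 1L
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  ok <- idx3[, 1] >= 1L & idx3[, 1] <= nx & idx3[, 2] >= 1L &
    idx3[, 2] <= ny & idx3[, 3] >= 1L & idx3[, 3] <= nz
  lin <- (jj[ok] - 1L) * nx * ny * nz + (idx3[ok, 3] - 1L) * nx * ny +
    (idx3[ok, 2] - 1L) * nx + idx3[ok, 1]
  list(lin = lin, wt = mass[ok])
}

#' Project the knowledge base into probability density maps
#'
#' For every contributing atom (surface protein atoms, types 1-30, with a
#' local frame), its probability-normalized canonical histograms are
#' rigid-transformed by the atom's frame and splatted into the global
#' grids; the accumulated maps are divided by the number of contributing
#' atoms and cells inside the protein van der Waals volume are zeroed.
#'
#' @param query a typed `ppi_structure` with SASA computed.
#' @param kb a `ppi_kb`.
#' @param grid a `ppi_grid` (default: [grid_for_structure()]).
#' @param frames optional precomputed [structure_frames()].
#' @param occupancy optional precomputed [compute_occupancy()]; set
#'   `mask = FALSE` to skip masking entirely.
#' @param mode `"trilinear"` (mass-conserving splat, default) or
#'   `"nearest"` (single-cell deposits, used by oracle tests).
#' @param mask zero cells occupied by the protein (default TRUE).
#' @return list with `values` (array nx x ny x nz x 31), `grid`,
#'   `n_contributing`, and `skipped` (atoms without frames).
#' @export
project_pdms <- function(query, kb, grid = grid_for_structure(query),
                         frames = NULL, occupancy = NULL,
                         mode = c("trilinear", "nearest"), mask = TRUE) {
  mode <- match.arg(mode)
  a <- query$atoms
  if (anyNA(a$sasa_u) && nrow(a)) stop("SASA not computed on query")
  if (is.null(frames)) frames <- structure_frames(query)
  values <- array(0, c(grid$dims, 31L))
  contrib <- which(!is.na(a$type) & a$type <= 30L & a$sasa_u > 0)
  skipped <- contrib[vapply(frames[contrib], is.null, logical(1))]
  contrib <- setdiff(contrib, skipped)
  if (length(skipped))
    warning(length(skipped), " surface atom(s) without a local frame skipped")
  if (!length(contrib))
    return(list(values = values, grid = grid, n_contributing = 0L,
                skipped = skipped))
  # per center type: one sparse table of (j, local x/y/z, normalized mass)
  tabs <- lapply(1:30, function(t) {
    cc <- kb$cells[kb$cells$center_type == t, , drop = FALSE]
    if (!nrow(cc)) return(NULL)
    tot <- kb$totals[t, cc$partner_type]
    data.frame(j = cc$partner_type,
               x = (cc$ix - 0.5) * kb$spacing - kb$extent,
               y = (cc$iy - 0.5) * kb$spacing - kb$extent,
               z = (cc$iz - 0.5) * kb$spacing - kb$extent,
               mass = cc$n / tot)
  })
  xyz <- coords(query)
  splat <- if (mode == "trilinear") splat_trilinear else splat_nearest
  acc <- vector("list", length(contrib))
  for (k in seq_along(contrib)) {
    i <- contrib[k]
    tab <- tabs[[a$type[i]]]
    if (is.null(tab)) next
    fr <- frames[[i]]
    pts <- cbind(tab$x, tab$y, tab$z) %*% t(fr$R)
    pts[, 1] <- pts[, 1] + xyz[i, 1]
    pts[, 2] <- pts[, 2] + xyz[i, 2]
    pts[, 3] <- pts[, 3] + xyz[i, 3]
    u <- grid_frame_coords(grid, pts)
    acc[[k]] <- splat(grid, u, tab$j, tab$mass)
  }
  lin <- unlist(lapply(acc, `[[`, "lin"))
  if (length(lin)) {
    add <- rowsum(unlist(lapply(acc, `[[`, "wt")), lin)
    values[as.numeric(rownames(add))] <- add[, 1]
  }
  values <- values / length(contrib)
  if (mask) {
    if (is.null(occupancy)) occupancy <- compute_occupancy(query, grid)
    values[rep(as.logical(occupancy), 31L)] <- 0
  }
  list(values = values, grid = grid, n_contributing = length(contrib),
       skipped = skipped)
}

#' Export one density map in OpenDX format
#'
#' Writes map `j` of a [project_pdms()] result as an OpenDX scalar field
#' readable by common molecular viewers.  Only identity-oriented grids are
#' supported.
#'
#' @param pdms result of [project_pdms()].
#' @param j interacting atom type (1-31).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pdm_dx <- function(pdms, j, file) {
  g <- pdms$grid
  if (max(abs(g$orientation - diag(3))) > 1e-12)
    stop("OpenDX export supports identity-oriented grids only")
  d <- g$dims
  v <- pdms$values[, , , j]
  con <- file(file, "w")
  on.exit(close(con))
  o <- g$origin + 0.5 * g$spacing
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", o[1], o[2], o[3]),
    sprintf("delta %.4f 0 0", g$spacing),
    sprintf("delta 0 %.4f 0", g$spacing),
    sprintf("delta 0 0 %.4f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(paste("object 3 class array type double rank 0 items %d",
                  "data follows"), prod(d))), con)
  # DX order: x fastest loop is z
  vals <- as.numeric(aperm(v, c(1, 2, 3))[cbind(
    rep(seq_len(d[1]), each = d[2] * d[3]),
    rep(rep(seq_len(d[2]), each = d[3]), d[1]),
    rep(seq_len(d[3]), d[1] * d[2]))])
  writeLines(apply(matrix(c(sprintf("%.6e", vals),
                            rep("", (3 - length(vals) %% 3) %% 3)),
                          ncol = 3, byrow = TRUE), 1, paste, collapse = " "),
             con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(file)
}
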