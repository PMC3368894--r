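# Knowledge base of non-covalent contact statistics.
#
# Contacts between heavy atoms of reference structures are harvested under a
# distance rule d <= r_i + r_j + tolerance (tolerance 1.4 A, probe-sized),
# screened by the interaction filter, and binned into per
# (center type, partner type) 3D histograms expressed in each center atom's
# canonical local frame, which makes the statistics pose-invariant.

#' Harvest non-covalent interacting atom pairs from reference structures
#'
#' Excluded pairs: same residue, covalently bonded and 1-3/1-4 neighbours
#' (graph distance <= 3), type pairs rejected by the filter, untyped atoms.
#' Each admitted pair yields one observation per eligible center: the
#' center must be a protein atom (type 1-30) with a local frame; water
#' (type 31) can only ever be a partner.  With `strict_interior = TRUE`
#' only pairs in which both atoms are solvent-inaccessible (SASA_u = 0)
#' are kept, so that the statistics describe the protein interior.
#'
#' @param reference a `ppi_structure` or list of them, typed.
#' @param filter a `ppi_filter`.
#' @param tolerance contact-rule tolerance in Angstrom (default 1.4).
#' @param strict_interior restrict to buried-buried pairs (default TRUE).
#' @param probe,points SASA settings used when `strict_interior` and SASA
#'   is not yet present.
#' @return data.frame of observations: center_type, partner_type, dx, dy,
#'   dz (displacement in the center's local frame), structure id.
#' @export
harvest_contacts <- function(reference, filter, tolerance = 1.4,
                             strict_interior = TRUE, probe = 1.4,
                             points = 960) {
  if (inherits(reference, "ppi_structure")) reference <- list(reference)
  obs <- vector("list", length(reference))
  for (s in seq_along(reference)) {
    st <- reference[[s]]
    a <- st$atoms
    if (all(is.na(a$type))) stop("reference structure ", s, " is untyped")
    if (strict_interior && anyNA(a$sasa_u))
      a$sasa_u <- compute_sasa(st, probe, points)
    adj <- bond_graph(st)
    if (!any(lengths(adj) > 0))
      stop("reference structure ", s,
           " has no covalent topology; cannot exclude bonded pairs")
    frames <- structure_frames(st, adj)
    xyz <- coords(st)
    n <- nrow(a)
    rad <- a$radius
    typ <- a$type
    # candidate pairs by distance rule
    d <- as.matrix(stats::dist(xyz))
    cutoff <- outer(rad, rad, "+") + tolerance
    cand <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    i <- cand[, 1]; j <- cand[, 2]
    keep <- !is.na(typ[i]) & !is.na(typ[j]) &
      !(a$chain[i] == a$chain[j] & a$resno[i] == a$resno[j]) &
      filter_admits(filter, typ[i], typ[j])
    if (strict_interior) keep <- keep & a$sasa_u[i] == 0 & a$sasa_u[j] == 0
    i <- i[keep]; j <- j[keep]
    # drop covalent 1-2/1-3/1-4 neighbours
    if (length(i)) {
      near <- mapply(function(p, q) q %in% graph_neighbourhood(adj, p, 3), i, j)
      i <- i[!near]; j <- j[!near]
    }
    if (!length(i)) next
    one_dir <- function(ci, pj) {
      ok <- typ[ci] <= 30L & !vapply(frames[ci], is.null, logical(1))
      ci <- ci[ok]; pj <- pj[ok]
      if (!length(ci)) return(NULL)
      disp <- t(vapply(seq_along(ci), function(k) {
        fr <- frames[[ci[k]]]
        as.numeric(crossprod(fr$R, xyz[pj[k], ] - fr$origin))
      }, numeric(3)))
      data.frame(center_type = typ[ci], partner_type = typ[pj],
                 dx = disp[, 1], dy = disp[, 2], dz = disp[, 3],
                 structure = s)
    }
    obs[[s]] <- rbind(one_dir(i, j), one_dir(j, i))
  }
  out <- do.call(rbind, obs)
  if (is.null(out))
    out <- data.frame(center_type = integer(), partner_type = integer(),
                      dx = numeric(), dy = numeric(), dz = numeric(),
                      structure = integer())
  rownames(out) <- NULL
  out
}

#' Accumulate pair observations into canonical-frame histograms
#'
#' Each observation increments exactly one cell of the (center type,
#' partner type) histogram: a cubic grid of the stated spacing covering
#' \[-extent, extent\] on each axis of the local frame.  Displacements
#' outside the extent are dropped and counted in the report.
#'
#' @param observations data.frame from [harvest_contacts()].
#' @param spacing cell edge in Angstrom (default 1.0).
#' @param extent half-width of the cube in Angstrom (default 8.0).
#' @param metadata optional list recorded with the knowledge base (contact
#'   rule, reference-set fingerprint, ...).
#' @return a `ppi_kb`: sparse per-(t,j) histograms plus totals.
#' @export
accumulate_histograms <- function(observations, spacing = 1.0, extent = 8.0,
                                  metadata = list()) {
  stopifnot(spacing > 0, extent > 0)
  ncell <- as.integer(round(2 * extent / spacing))
  ix <- floor((observations$dx + extent) / spacing) + 1L
  iy <- floor((observations$dy + extent) / spacing) + 1L
  iz <- floor((observations$dz + extent) / spacing) + 1L
  inside <- ix >= 1L & ix <= ncell & iy >= 1L & iy <= ncell &
    iz >= 1L & iz <= ncell
  dropped <- sum(!inside)
  o <- observations[inside, , drop = FALSE]
  ix <- ix[inside]; iy <- iy[inside]; iz <- iz[inside]
  key <- paste(o$center_type, o$partner_type, ix, iy, iz)
  if (length(key)) {
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- do.call(rbind, strsplit(as.character(agg$key), " "))
    cells <- data.frame(center_type = as.integer(parts[, 1]),
                        partner_type = as.integer(parts[, 2]),
                        ix = as.integer(parts[, 3]),
                        iy = as.integer(parts[, 4]),
                        iz = as.integer(parts[, 5]),
                        n = as.integer(agg$Freq))
  } else {
    cells <- data.frame(center_type = integer(), partner_type = integer(),
                        ix = integer(), iy = integer(), iz = integer(),
                        n = integer())
  }
  cells <- cells[order(cells$center_type, cells$partner_type,
                       cells$ix, cells$iy, cells$iz), ]
  rownames(cells) <- NULL
  totals <- matrix(0L, 30, 31, dimnames = list(1:30, 1:31))
  if (nrow(cells)) {
    tt <- stats::aggregate(n ~ center_type + partner_type, cells, sum)
    totals[cbind(tt$center_type, tt$partner_type)] <- tt$n
  }
  structure(list(cells = cells, totals = totals, spacing = spacing,
                 extent = extent, ncell = ncell, dropped = dropped,
                 metadata = metadata),
            class = "ppi_kb")
}

#' @export
print.ppi_kb <- function(x, ...) {
  cat(sprintf(
    "ppi_kb: %d observations in %d cells (%.1f A spacing, +/-%.1f A), %d dropped\n",
    sum(x$totals), nrow(x$cells), x$spacing, x$extent, x$dropped))
  invisible(x)
}

#' Sparse histogram of one (center type, partner type) pair
#'
#' @param kb a `ppi_kb`.
#' @param center_type,partner_type type IDs.
#' @param normalized divide counts by their sum (default TRUE); the
#'   normalized histogram sums to 1 whenever observations exist.
#' @return data.frame with local-frame cell centers (x, y, z) and `mass`.
#' @export
kb_histogram <- function(kb, center_type, partner_type, normalized = TRUE) {
  c0 <- kb$cells[kb$cells$center_type == center_type &
                   kb$cells$partner_type == partner_type, , drop = FALSE]
  mass <- as.numeric(c0$n)
  if (normalized && length(mass)) mass <- mass / sum(mass)
  data.frame(x = (c0$ix - 0.5) * kb$spacing - kb$extent,
             y = (c0$iy - 0.5) * kb$spacing - kb$extent,
             z = (c0$iz - 0.5) * kb$spacing - kb$extent,
             mass = mass)
}

#' Build a knowledge base from reference structures
#'
#' Convenience wrapper: [harvest_contacts()] then
#' [accumulate_histograms()], with the contact rule recorded in the
#' metadata.
#'
#' @inheritParams harvest_contacts
#' @inheritParams accumulate_histograms
#' @return a `ppi_kb`.
#' @export
build_knowledge_base <- function(reference, filter, tolerance = 1.4,
                                 strict_interior = TRUE, spacing = 1.0,
                                 extent = 8.0, probe = 1.4, points = 960) {
  obs <- harvest_contacts(reference, filter, tolerance, strict_interior,
                          probe, points)
  accumulate_histograms(obs, spacing, extent, metadata = list(
    contact_rule = sprintf("d <= r_i + r_j + %.2f", tolerance),
    strict_interior = strict_interior,
    n_structures = if (inherits(reference, "ppi_structure")) 1L
    else length(reference)))
}

#' Persist a knowledge base to a directory
#' @param kb a `ppi_kb`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_kb <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(kb$cells, file.path(dir, "kb_cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- c(kb$metadata, list(spacing = kb$spacing, extent = kb$extent,
                              ncell = kb$ncell, dropped = kb$dropped))
  jsonlite::write_json(meta, file.path(dir, "kb_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a knowledge base written by [write_kb()]
#' @param dir directory path.
#' @return a `ppi_kb`.
#' @export
read_kb <- function(dir) {
  cells <- utils::read.table(file.path(dir, "kb_cells.tsv"), sep = "\t",
                             header = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "kb_meta.json"),
                              simplifyVector = TRUE)
  kb <- accumulate_histograms(
    data.frame(center_type = integer(), partner_type = integer(),
               dx = numeric(), dy = numeric(), dz = numeric(),
               structure = integer()),
    spacing = meta$spacing, extent = meta$extent)
  kb$cells <- cells
  totals <- matrix(0L, 30, 31, dimnames = list(1:30, 1:31))
  if (nrow(cells)) {
    tt <- stats::aggregate(n ~ center_type + partner_type, cells, sum)
    totals[cbind(tt$center_type, tt$partner_type)] <- tt$n
  }
  kb$totals <- totals
  kb$dropped <- meta$dropped
  kb$metadata <- meta[setdiff(names(meta),
                              c("spacing", "extent", "ncell", "dropped"))]
  kb
}
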