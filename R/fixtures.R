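# Deterministic synthetic fixtures: idealized poly-peptide-like chains with
# two-sphere side-chain proxies, docked globule pairs with planted
# hydrophobic interfaces, and compact globules with spatially clustered
# hydrophobicity for knowledge-base construction.  All fixtures are pure
# functions of their seeds and exercise the real parsing/typing/SASA/
# contact code paths.

# residue alphabet of the fixtures: CB plus one representative distal
# side-chain atom per residue (and backbone N/CA/C/O), typed through the
# standard table
fixture_residues <- function() {
  data.frame(
    resname = c("LEU", "ILE", "VAL", "MET",
                "SER", "THR", "ASN", "GLN", "LYS", "ARG", "ASP", "GLU"),
    side_atom = c("CD1", "CD1", "CG1", "CE",
                  "OG", "OG1", "ND2", "NE2", "NZ", "NH1", "OD1", "OE1"),
    hydrophobic = c(rep(TRUE, 4), rep(FALSE, 8)),
    stringsAsFactors = FALSE
  )
}

unit <- function(v) v / sqrt(sum(v^2))

perp_of <- function(t) {
  ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unit(ref - sum(ref * t) * t)
}

# Build a full toy structure from a CA trace and a residue-name vector.
# Backbone C/N sit on the CA-CA virtual bonds with a +-0.45 A zigzag so
# that local frames are never collinear.  Side chains are two-sphere
# proxies pointing away from the two neighbouring CAs: a CB at 1.55 A and
# the residue's representative distal atom at 3.1 A, so that side-side
# packing contacts occur between residues as in real proteins.
build_toy_chain <- function(trace, resnames, chain = "A", resno_offset = 0L) {
  n <- nrow(trace)
  stopifnot(n >= 2L, length(resnames) == n)
  fr <- fixture_residues()
  side_atom <- fr$side_atom[match(resnames, fr$resname)]
  tb <- t(vapply(seq_len(n - 1), function(i)
    unit(trace[i + 1, ] - trace[i, ]), numeric(3)))
  pb <- t(vapply(seq_len(n - 1), function(i) perp_of(tb[i, ]), numeric(3)))
  sgn <- rep_len(c(1, -1), n)
  ia <- pmax(seq_len(n) - 1, 1)    # bond used for each residue's N
  ib <- pmin(seq_len(n), n - 1)    # bond used for each residue's C and O
  Nm <- trace - 1.2 * tb[ia, ] + 0.45 * sgn[ia] * pb[ia, ]
  Cm <- trace + 1.2 * tb[ib, ] - 0.45 * sgn * pb[ib, ]
  qm <- t(vapply(seq_len(n), function(i)
    unit(pracma_cross(tb[ib[i], ], pb[ib[i], ])), numeric(3)))
  Om <- Cm + 1.23 * qm
  dm <- t(vapply(seq_len(n), function(i) {
    d <- (trace[i, ] - trace[ia[i], ]) + (trace[i, ] - trace[pmin(i + 1, n), ])
    if (sqrt(sum(d^2)) < 0.2) pb[ib[i], ] else unit(d)
  }, numeric(3)))
  CBm <- trace + 1.55 * dm
  # distal sphere bent ~25 degrees off the CA-CB axis (like a side-chain
  # chi angle); the bend also keeps CA-CB-tip non-collinear so every side
  # atom gets a canonical local frame
  em <- t(vapply(seq_len(n), function(i) {
    e <- qm[i, ] - sum(qm[i, ] * dm[i, ]) * dm[i, ]
    if (sqrt(sum(e^2)) < 0.2) e <- pb[ib[i], ] - sum(pb[ib[i], ] * dm[i, ]) * dm[i, ]
    unit(e)
  }, numeric(3)))
  TIPm <- CBm + 1.55 * (cos(25 * pi / 180) * dm + sin(25 * pi / 180) * em)
  per <- 6L
  xyz <- matrix(0, n * per, 3)
  xyz[seq(1, n * per, per), ] <- Nm
  xyz[seq(2, n * per, per), ] <- trace
  xyz[seq(3, n * per, per), ] <- Cm
  xyz[seq(4, n * per, per), ] <- Om
  xyz[seq(5, n * per, per), ] <- CBm
  xyz[seq(6, n * per, per), ] <- TIPm
  atoms <- data.frame(
    chain = chain,
    resno = rep(seq_len(n) + resno_offset, each = per),
    resname = rep(resnames, each = per),
    atom = as.vector(rbind("N", "CA", "C", "O", "CB", side_atom)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE)
  ppi_structure(atoms, provenance = "synthetic")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# compact confined self-avoiding CA walk.  The confinement is a ball of
# `radius` intersected with the half-space z >= zmin (zmin = -Inf gives a
# full globule; a finite zmin gives a dome with a flat face used for
# docked complexes).
walk_trace <- function(n, seed, step = 3.8, min_sep = 6.0,
                       radius = 4.5 * n^(1/3), zmin = -Inf, tries = 120) {
  set.seed(seed)
  z0 <- if (is.finite(zmin)) zmin + 0.5 else 0
  for (restart in 1:40) {
    tr <- matrix(NA_real_, n, 3)
    tr[1, ] <- c(0, 0, z0)
    tr[2, ] <- c(step, 0, z0)
    ok <- TRUE
    for (i in 3:n) {
      placed <- FALSE
      for (k in seq_len(tries)) {
        dir <- stats::rnorm(3)
        dir <- unit(dir - 0.35 * tr[i - 1, ] / radius)  # centripetal bias
        cand <- tr[i - 1, ] + step * dir
        if (sqrt(sum(cand^2)) > radius || cand[3] < zmin) next
        # no sharp turns: i, i+2 CA pairs keep 5.5 A (prevents backbone
        # carbonyl/amide congestion around the intervening residue)
        if (sum((cand - tr[i - 2, ])^2) < 5.5^2) next
        d2 <- rowSums((tr[seq_len(i - 2), , drop = FALSE] -
                         matrix(cand, i - 2, 3, byrow = TRUE))^2)
        if (min(d2) < min_sep^2) next
        tr[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(tr)
  }
  stop("could not grow a clash-free walk of length ", n)
}

# non-bonded clash check: atoms of residues at least 2 apart in sequence
# (or on different chains) must keep >= factor * (vdW radius sum)
assert_clash_free <- function(structure, factor = 0.8) {
  st <- assign_atom_types(structure)
  a <- st$atoms
  xyz <- coords(st)
  d <- as.matrix(stats::dist(xyz))
  rs <- outer(a$radius, a$radius, "+") * factor
  same_chain <- outer(a$chain, a$chain, "==")
  close_seq <- same_chain & abs(outer(a$resno, a$resno, "-")) <= 1
  bad <- d < rs & upper.tri(d) & !close_seq
  if (any(bad, na.rm = TRUE))
    stop("steric clash in generated fixture (",
         sum(bad, na.rm = TRUE), " pair(s))")
  invisible(structure)
}

draw_sequence <- function(hydro_prob) {
  fr <- fixture_residues()
  hydro <- fr$resname[fr$hydrophobic]
  polar <- fr$resname[!fr$hydrophobic]
  vapply(hydro_prob, function(p) {
    if (stats::runif(1) < p) sample(hydro, 1) else sample(polar, 1)
  }, character(1))
}

#' Generate a toy two-chain complex with a planted hydrophobic interface
#'
#' Each chain is a compact "dome": a confined self-avoiding walk filling a
#' hemisphere, so the body is thicker than the 10 A feature kernels and the
#' flat face is a genuine surface patch.  The two domes are docked face to
#' face along the contact plane, the second chain mirrored in z.  Residues
#' whose side-chain sphere sits near the contact plane are the planted
#' interface; they draw hydrophobic residue types with probability
#' `background + enrichment` (so zero enrichment reproduces the background
#' composition), all other residues with probability `background`.
#'
#' The docking offset is scanned outward from close contact until the
#' complex is clash-free (non-bonded pairs from non-adjacent residues keep
#' at least 0.8 of the van der Waals radius sum) while the planted faces
#' still bury surface area (dSASA > 0) on complexation.
#'
#' @param n_res residues per chain (>= 5; default 48).
#' @param enrichment excess hydrophobic probability at the planted
#'   interface over the background (default 0.8).
#' @param background hydrophobic probability elsewhere (default 0.15).
#' @param seed RNG seed; coordinates and sequence are pure functions of it.
#' @return list with `unbound` (list of the two single-chain structures),
#'   `complexed` (merged typed structure), and `planted` (data.frame of
#'   chain/resno flags for the planted interface residues).
#' @export
generate_toy_complex <- function(n_res = 48, enrichment = 0.8,
                                 background = 0.15, seed = 1) {
  stopifnot(n_res >= 5)
  dome <- function(sd) {
    for (attempt in 0:200) {
      tr <- tryCatch(walk_trace(n_res, seed = sd + attempt * 100000,
                                zmin = 1.2),
                     error = function(e) NULL)
      if (is.null(tr)) next
      # side-sphere directions (bisector rule of build_toy_chain)
      side_z <- vapply(seq_len(n_res), function(i) {
        ia <- max(i - 1, 1); ic <- min(i + 1, n_res)
        d <- (tr[i, ] - tr[ia, ]) + (tr[i, ] - tr[ic, ])
        if (sqrt(sum(d^2)) < 0.2) return(NA_real_)
        tr[i, 3] + 3.1 * unit(d)[3]
      }, numeric(1))
      face <- !is.na(side_z) & side_z < 1.6
      if (sum(face) < 4) next
      # internal clash check with the largest (carbon) side-sphere radii;
      # the z-mirrored trace is checked too because the backbone builder's
      # perpendicular references are not mirror-symmetric and the second
      # chain of a complex is docked mirrored
      ok <- all(vapply(list(tr, tr %*% diag(c(1, 1, -1))), function(tt) {
        probe_chain <- assign_atom_types(
          build_toy_chain(tt, rep("LEU", n_res), chain = "A"))
        tryCatch({ assert_clash_free(probe_chain); TRUE },
                 error = function(e) FALSE)
      }, logical(1)))
      if (ok) return(list(tr = tr, face = face,
                          seed_used = sd + attempt * 100000))
    }
    stop("could not grow a dome with a usable contact face")
  }
  A <- dome(seed * 10 + 1)
  B <- dome(seed * 10 + 2)
  recenter <- function(d) {
    ctr <- colMeans(d$tr[d$face, , drop = FALSE])
    d$tr[, 1] <- d$tr[, 1] - ctr[1]
    d$tr[, 2] <- d$tr[, 2] - ctr[2]
    d
  }
  A <- recenter(A); B <- recenter(B)
  set.seed(seed * 10 + 3)
  face_prob <- min(1, background + enrichment)
  # the enriched region is the whole slab under the contact face (surface
  # face residues plus the sub-surface layer), mimicking interface cores
  # that resemble protein interiors in composition
  slab <- function(d) d$face | d$tr[, 3] < 4.7
  seqA <- draw_sequence(ifelse(slab(A), face_prob, background))
  seqB <- draw_sequence(ifelse(slab(B), face_prob, background))
  chA <- assign_atom_types(build_toy_chain(A$tr, seqA, chain = "A"))
  # chain B is built once from the z-mirrored trace; docking then only
  # translates it.  A small lateral-offset search lets the protruding
  # side chains of the two faces interdigitate: for each offset the
  # closest clash-free vertical gap is found, and the pose with the most
  # cross-chain contact pairs wins.
  trBm <- B$tr
  trBm[, 3] <- -trBm[, 3]
  chB0 <- assign_atom_types(build_toy_chain(trBm, seqB, chain = "B"))
  xyzA <- coords(chA); radA <- chA$atoms$radius
  xyzB0 <- coords(chB0); radB <- chB0$atoms$radius
  rsum08 <- 0.8 * outer(radA, radB, "+")
  rcontact <- outer(radA, radB, "+") + 1.4
  best <- NULL
  for (off in list(c(0, 0), c(2.5, 0), c(-2.5, 0), c(0, 2.5), c(0, -2.5),
                   c(2.5, 2.5), c(-2.5, 2.5), c(2.5, -2.5), c(-2.5, -2.5))) {
    for (gap in seq(-1.0, -12.0, -0.25)) {
      xb <- xyzB0
      xb[, 1] <- xb[, 1] + off[1]
      xb[, 2] <- xb[, 2] + off[2]
      xb[, 3] <- xb[, 3] + gap
      d2 <- outer(rowSums(xyzA^2), rowSums(xb^2), "+") -
        2 * xyzA %*% t(xb)
      d <- sqrt(pmax(d2, 0))
      if (any(d < rsum08)) next
      contacts <- sum(d <= rcontact)
      if (is.null(best) || contacts > best$contacts)
        best <- list(off = off, gap = gap, contacts = contacts)
      break                          # closest clash-free gap for this offset
    }
  }
  if (!is.null(best)) {
    gap <- best$gap
    chB <- transform_structure(chB0, t = c(best$off[1], best$off[2], gap))
    cplx <- assign_atom_types(merge_structures(chA, chB))
    ok <- tryCatch({ assert_clash_free(cplx); TRUE },
                   error = function(e) FALSE)
    if (ok) {
      # planted residues: face residues whose side sphere ends up within
      # guaranteed burial range (5.5 A) of a partner atom after docking
      ca <- cplx$atoms
      side_rows <- !(ca$atom %in% c("N", "CA", "C", "O", "CB"))
      near_partner <- function(ch, face) {
        own <- which(side_rows & ca$chain == ch)
        other <- as.matrix(ca[ca$chain != ch, c("x", "y", "z")])
        buried <- vapply(own, function(i) {
          min(sqrt(colSums((t(other) - as.numeric(ca[i, c("x", "y", "z")]))^2)))
        }, numeric(1)) <= 5.5
        flag <- logical(n_res)
        flag[ca$resno[own[buried]]] <- TRUE
        flag & face
      }
      planted <- rbind(
        data.frame(chain = "A", resno = seq_len(n_res),
                   planted = near_partner("A", A$face)),
        data.frame(chain = "B", resno = seq_len(n_res),
                   planted = near_partner("B", B$face)))
      return(list(unbound = list(A = chA, B = chB), complexed = cplx,
                  planted = planted, gap = gap))
    }
  }
  stop("could not dock the two chains without steric clash")
}

#' Generate compact globular toy structures for knowledge-base building
#'
#' Confined self-avoiding walks with spatially clustered hydrophobicity:
#' a random hemisphere of each globule draws hydrophobic residue types
#' with probability 0.85 (0.15 in the other hemisphere), modulated by a
#' buried-core bias -- giving the hydrophobic-with-hydrophobic contact
#' enrichment that knowledge-based statistics rely on in real protein
#' interiors, at desk scale.
#'
#' @param n number of structures.
#' @param n_res residues per structure (default 40).
#' @param seed base seed; structure s uses seed * 100 + s.
#' @return list of typed `ppi_structure` objects.
#' @export
generate_reference_set <- function(n, n_res = 40, seed = 1) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(s) {
    for (attempt in 0:200) {
      sd <- seed * 100 + s + attempt * 100000
      tr <- tryCatch(walk_trace(n_res, seed = sd), error = function(e) NULL)
      if (is.null(tr)) next
      set.seed(sd + 7)
      # spatially clustered hydrophobicity: a hydrophobic patch (random
      # hemisphere) with a buried core bias, so hydrophobic atoms contact
      # hydrophobic atoms preferentially, as in real protein interiors
      ctr <- sweep(tr, 2, colMeans(tr))
      u <- unit(stats::rnorm(3))
      r <- sqrt(rowSums(ctr^2))
      hydro_p <- ifelse(ctr %*% u > 0, 0.85, 0.15) +
        ifelse(r <= stats::median(r), 0.1, -0.1)
      seqs <- draw_sequence(pmin(0.95, pmax(0.05, hydro_p)))
      st <- assign_atom_types(build_toy_chain(tr, seqs, chain = "A"))
      ok <- tryCatch({ assert_clash_free(st); TRUE },
                     error = function(e) FALSE)
      if (ok) {
        st$provenance <- sprintf("synthetic globule seed=%d", sd)
        return(st)
      }
    }
    stop("could not generate a clash-free globule for index ", s)
  })
}
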