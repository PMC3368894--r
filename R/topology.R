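# Covalent topology, backbone completeness, and canonical local frames.
#
# Bonds are inferred with an element-aware distance rule (C/N/O pairs within
# 1.9 A, pairs involving sulfur within 2.3 A, same or adjacent residue of the
# same chain, never N-N / N-O / O-O), which reproduces residue-template
# connectivity on standard amino acids and also holds for the idealized
# synthetic fixtures.  Water is never bonded.

atom_element <- function(atom_name) {
  substr(gsub("^[0-9]*", "", toupper(atom_name)), 1, 1)
}

#' Covalent bond list of a structure
#'
#' @param structure a `ppi_structure`.
#' @return adjacency list: for each atom, the integer indices of its
#'   covalently bonded heavy neighbours.
#' @export
bond_graph <- function(structure) {
  a <- structure$atoms
  n <- nrow(a)
  adj <- vector("list", n)
  if (n == 0L) return(adj)
  ele <- atom_element(a$atom)
  water <- a$resname %in% c("HOH", "WAT", "DOD")
  xyz <- coords(structure)
  cut2 <- function(e1, e2) ifelse(e1 == "S" | e2 == "S", 2.3, 1.9)^2
  ok_pair <- function(e1, e2) {
    (e1 == "C" | e2 == "C") | (e1 == "S" & e2 == "S")
  }
  for (i in seq_len(n)) {
    if (water[i]) next
    cand <- which(a$chain == a$chain[i] & abs(a$resno - a$resno[i]) <= 1 &
                    seq_len(n) > i & !water)
    if (!length(cand)) next
    d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
      (xyz[cand, 3] - xyz[i, 3])^2
    hit <- cand[d2 <= cut2(ele[i], ele[cand]) & ok_pair(ele[i], ele[cand])]
    if (length(hit)) {
      adj[[i]] <- c(adj[[i]], hit)
      for (j in hit) adj[[j]] <- c(adj[[j]], i)
    }
  }
  lapply(adj, function(v) sort(unique(v)))
}

# graph distance <= k neighbourhood (used for 1-2/1-3/1-4 exclusions)
graph_neighbourhood <- function(adj, i, k = 3) {
  seen <- i
  frontier <- i
  for (step in seq_len(k)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  setdiff(seen, i)
}

#' Residues with complete phi and psi angles
#'
#' A residue's phi is defined when the preceding residue's backbone C lies
#' within peptide-bond distance (2.0 A) of its N; psi when the following
#' residue's N lies within 2.0 A of its C.  Chain termini and chain breaks
#' therefore drop out, mirroring the exclusion of such residues from
#' prediction.
#'
#' @param structure a `ppi_structure`.
#' @param bond_max maximum peptide C-N distance (Angstrom).
#' @return data.frame with chain, resno and a logical `phipsi_ok`.
#' @export
phipsi_complete <- function(structure, bond_max = 2.0) {
  a <- structure$atoms
  res <- unique(a[, c("chain", "resno")])
  get <- function(ch, rn, nm) {
    i <- which(a$chain == ch & a$resno == rn & a$atom == nm)
    if (length(i)) as.numeric(a[i[1], c("x", "y", "z")]) else NULL
  }
  ok <- logical(nrow(res))
  for (k in seq_len(nrow(res))) {
    ch <- res$chain[k]; rn <- res$resno[k]
    nN <- get(ch, rn, "N"); cC <- get(ch, rn, "C"); ca <- get(ch, rn, "CA")
    prevC <- get(ch, rn - 1L, "C"); nextN <- get(ch, rn + 1L, "N")
    ok[k] <- !is.null(nN) && !is.null(cC) && !is.null(ca) &&
      !is.null(prevC) && !is.null(nextN) &&
      sqrt(sum((nN - prevC)^2)) <= bond_max &&
      sqrt(sum((cC - nextN)^2)) <= bond_max
  }
  res$phipsi_ok <- ok
  res
}

#' Canonical local frame of an atom
#'
#' Right-handed orthonormal frame anchored on the atom, built from its
#' covalently bonded neighbours (sorted by chain, residue number and atom
#' name for determinism).  Terminal atoms with a single bonded neighbour
#' borrow that neighbour's own second neighbour as the secondary reference.
#' The frame makes contact histograms pose-invariant: the frame of a
#' rotated structure equals the rotated frame.
#'
#' @param structure a `ppi_structure`.
#' @param i atom index.
#' @param adj adjacency list from [bond_graph()].
#' @return list(origin, R) where the columns of R are the frame axes, or
#'   NULL when no frame can be built (fewer than 1 bonded neighbour, or all
#'   references collinear).
#' @export
build_local_frame <- function(structure, i, adj = bond_graph(structure)) {
  a <- structure$atoms
  xyz <- coords(structure)
  order_atoms <- function(idx) {
    idx[order(a$chain[idx], a$resno[idx], a$atom[idx])]
  }
  nb <- order_atoms(adj[[i]])
  if (length(nb) < 1L) return(NULL)
  refs <- nb
  if (length(refs) < 2L) {
    second <- order_atoms(setdiff(adj[[nb[1]]], i))
    refs <- c(refs, second)
  }
  if (length(refs) < 2L) return(NULL)
  o <- xyz[i, ]
  e1 <- xyz[refs[1], ] - o
  e1 <- e1 / sqrt(sum(e1^2))
  for (r in refs[-1]) {
    v <- xyz[r, ] - o
    v <- v - sum(v * e1) * e1
    nv <- sqrt(sum(v^2))
    if (nv > 1e-6) {
      e2 <- v / nv
      e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      return(list(origin = o, R = cbind(e1, e2, e3, deparse.level = 0)))
    }
  }
  NULL
}

#' Local frames for all atoms of a structure
#'
#' @param structure a `ppi_structure`.
#' @param adj optional precomputed [bond_graph()].
#' @return list of frames (NULL where unavailable), one per atom.
#' @export
structure_frames <- function(structure, adj = bond_graph(structure)) {
  lapply(seq_len(n_atoms(structure)), function(i)
    build_local_frame(structure, i, adj))
}
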