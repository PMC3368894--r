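# Surface patch calling and residue-level conversion.
#
# Atoms whose positive-prediction confidence exceeds the seed threshold
# (60%) act as cluster centres; each collects surface atoms within 11 A
# whose confidence exceeds the member threshold (20%).  Patches whose seeds
# come within 10 A are merged transitively (single linkage over seeds),
# the only order-independent reading of pairwise merging.

#' Cluster confident surface atoms into interface patches
#'
#' @param xyz coordinate matrix of the candidate surface atoms.
#' @param confidence per-atom positive-prediction confidence in \[0, 1\].
#' @param seed_threshold seeds have confidence strictly above this
#'   (default 0.6).
#' @param grow_radius membership radius around a seed (default 11 A).
#' @param member_threshold members have confidence strictly above this
#'   (default 0.2).
#' @param merge_distance seed-pair distance at or below which patches merge
#'   (default 10 A).
#' @return list of patches: `seeds`, `members` (row indices into xyz,
#'   seeds included), `center` (mean member coordinate).  Empty list when
#'   no seed exists.
#' @export
call_patches <- function(xyz, confidence, seed_threshold = 0.6,
                         grow_radius = 11.0, member_threshold = 0.2,
                         merge_distance = 10.0) {
  xyz <- as.matrix(xyz)
  seeds <- which(confidence > seed_threshold)
  if (!length(seeds)) return(list())
  # single-linkage components over seeds
  comp <- seq_along(seeds)
  if (length(seeds) > 1L) {
    d <- as.matrix(stats::dist(xyz[seeds, , drop = FALSE]))
    repeat {
      changed <- FALSE
      for (a in seq_along(seeds)) {
        link <- which(d[a, ] <= merge_distance)
        tgt <- min(comp[link])
        if (any(comp[link] != tgt)) {
          comp[comp %in% comp[link]] <- tgt
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  eligible <- which(confidence > member_threshold)
  lapply(sort(unique(comp)), function(cid) {
    s <- seeds[comp == cid]
    near <- vapply(eligible, function(i)
      min(sqrt(colSums((t(xyz[s, , drop = FALSE]) - xyz[i, ])^2))) <=
        grow_radius, logical(1))
    members <- sort(unique(c(s, eligible[near])))
    list(seeds = s, members = members,
         center = colMeans(xyz[members, , drop = FALSE]))
  })
}

residue_fraction_calls <- function(structure, member_flag, fraction) {
  a <- structure$atoms
  surf <- isTRUE_vec(a$is_surface)
  key <- paste(a$chain, a$resno)
  res <- unique(key[surf])
  n_surface <- vapply(res, function(r) sum(surf & key == r), numeric(1))
  n_hit <- vapply(res, function(r) sum(surf & key == r & member_flag),
                  numeric(1))
  out <- data.frame(chain = sub(" .*", "", res),
                    resno = as.integer(sub(".* ", "", res)),
                    n_surface = n_surface, n_hit = n_hit,
                    fraction = n_hit / n_surface)
  out$positive <- out$fraction > fraction   # strictly greater
  rownames(out) <- NULL
  out
}

#' Residue-level predictions from atom patches
#'
#' A residue is called positive when strictly more than `fraction`
#' (default 30%) of its surface atoms (SASA_u > 0) belong to a predicted
#' patch.  Residues without surface atoms are excluded.
#'
#' @param patches result of [call_patches()].
#' @param structure the annotated structure the patch atom indices refer
#'   to (via `atom_index`).
#' @param atom_index integer atom rows (into `structure$atoms`)
#'   corresponding to the rows of the patch-calling coordinate matrix.
#' @param fraction residue-call fraction threshold (default 0.3).
#' @return data.frame of residue calls with `positive` flags.
#' @export
residues_from_patches <- function(patches, structure, atom_index,
                                  fraction = 0.3) {
  member_atoms <- unique(unlist(lapply(patches, function(p)
    atom_index[p$members])))
  flag <- seq_len(n_atoms(structure)) %in% member_atoms
  residue_fraction_calls(structure, flag, fraction)
}

#' Actual residue-level PPI sites
#'
#' The same 30% rule applied to the ground truth: a residue is an actual
#' PPI-site residue when strictly more than `fraction` of its surface
#' atoms have dSASA > 0.
#'
#' @param structure a structure labelled by [label_ppi_atoms()].
#' @param fraction residue-call fraction threshold (default 0.3).
#' @return data.frame of residue truth calls.
#' @export
actual_residue_sites <- function(structure, fraction = 0.3) {
  a <- structure$atoms
  if (all(is.na(a$dsasa)))
    stop("dSASA labels missing; run label_ppi_atoms() first")
  residue_fraction_calls(structure, isTRUE_vec(a$dsasa > 0), fraction)
}
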