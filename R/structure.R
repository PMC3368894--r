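#' Build a ppi_structure from an atom table
#'
#' Low-level constructor used by the parser and by the synthetic fixture
#' generators.  Atoms must be unique by (chain, residue number, atom name)
#' and coordinates finite.
#'
#' @param atoms data.frame with columns chain, resno, resname, atom, x, y, z.
#' @param provenance free-form character tag recording the source.
#' @return an object of class `ppi_structure`.
#' @export
ppi_structure <- function(atoms, provenance = "constructed") {
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  atoms <- atoms[, union(need, names(atoms))]
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate atoms by (chain, resno, atom): ",
         paste(utils::head(key[duplicated(key)], 5), collapse = "; "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in structure")
  for (col in c("type", "radius", "sasa_u", "sasa_c", "dsasa"))
    if (is.null(atoms[[col]])) atoms[[col]] <- rep(NA_real_, nrow(atoms))
  atoms$type <- as.integer(atoms$type)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, provenance = provenance),
            class = "ppi_structure")
}

#' @export
print.ppi_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("ppi_structure: %d atoms, %d residues, chains %s [%s]\n",
              nrow(a), length(unique(paste(a$chain, a$resno))),
              paste(sort(unique(a$chain)), collapse = ","), x$provenance))
  invisible(x)
}

#' Number of atoms in a structure
#' @param x a `ppi_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Coordinate matrix of a structure
#' @param x a `ppi_structure`.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(x) as.matrix(x$atoms[, c("x", "y", "z")])

#' Parse a protein structure from PDB format
#'
#' Reads ATOM/HETATM records through `bio3d::read.pdb`.  Hydrogens (and
#' deuteriums) are discarded.  Alternate locations are resolved by keeping
#' the highest-occupancy conformer, first-in-file on ties.  Crystal water
#' (HOH/WAT/DOD HETATM oxygen) is retained as candidate type-31 sites only
#' when `keep_water = TRUE`.
#'
#' @param pdb path to a PDB file, or PDB-format text (a string containing
#'   newlines, or a character vector of record lines).
#' @param chains optional character vector of author chain IDs to keep; an
#'   error names any requested chain with no atoms.
#' @param keep_water keep crystal-water oxygens (default FALSE).
#' @return a [ppi_structure()].
#' @export
parse_structure <- function(pdb, chains = NULL, keep_water = FALSE) {
  src <- "pdb"
  if (length(pdb) > 1L || grepl("\n", pdb[1]) ||
      grepl("^(ATOM|HETATM|HEADER|REMARK|MODEL)", pdb[1])) {
    f <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), f)
    on.exit(unlink(f))
    src <- "text"
  } else {
    if (!file.exists(pdb)) stop("no such PDB file: ", pdb)
    f <- pdb
    src <- pdb
  }
  p <- tryCatch(bio3d::read.pdb(f, verbose = FALSE, rm.alt = FALSE),
                error = function(e) stop("malformed PDB input: ",
                                         conditionMessage(e), call. = FALSE))
  at <- p$atom
  water <- at$type == "HETATM" & at$resid %in% c("HOH", "WAT", "DOD")
  at <- at[at$type == "ATOM" | water, , drop = FALSE]
  if (!keep_water) at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  # drop hydrogens by element symbol, falling back to the atom-name convention
  ele <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                               substr(gsub("^[0-9]", "", at$elety), 1, 1),
                               at$elesy)))
  at <- at[!(ele %in% c("H", "D")), , drop = FALSE]
  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(at$chain))
    if (length(missing))
      stop("no atoms for requested chain(s): ", paste(missing, collapse = ", "))
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  if (nrow(at) == 0L) {
    warning("no heavy atoms retained from PDB input")
    return(ppi_structure(data.frame(chain = character(), resno = integer(),
                                    resname = character(), atom = character(),
                                    x = numeric(), y = numeric(), z = numeric()),
                         provenance = src))
  }
  # alternate locations: highest occupancy wins, ties to first in file
  at$occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(factor(key, levels = unique(key)), -at$occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), , drop = FALSE]
  ppi_structure(data.frame(chain = at$chain, resno = at$resno,
                           resname = at$resid, atom = at$elety,
                           x = at$x, y = at$y, z = at$z,
                           stringsAsFactors = FALSE),
                provenance = src)
}

#' Write a structure to a PDB file
#'
#' Coordinates are written at standard PDB precision (3 decimal places).
#'
#' @param structure a `ppi_structure`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(structure, file) {
  a <- structure$atoms
  het <- a$resname %in% c("HOH", "WAT", "DOD")
  bio3d::write.pdb(file = file, xyz = as.numeric(t(coords(structure))),
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   elety = a$atom, o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(file)
}

#' Combine chains/structures into one structure
#'
#' Used to assemble a complexed form from its component chains.
#'
#' @param ... `ppi_structure` objects with disjoint (chain, resno, atom) keys.
#' @return a single merged `ppi_structure`.
#' @export
merge_structures <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "ppi_structure")) parts <- parts[[1]]
  atoms <- do.call(rbind, lapply(parts, function(s) s$atoms))
  ppi_structure(atoms, provenance = "merged")
}

#' Write the per-atom table as TSV
#'
#' One row per atom: chain, resno, resname, atom, type, SASA (unbound and
#' complexed), dSASA and the surface/predictable flags.
#'
#' @param structure an annotated `ppi_structure`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_atom_table <- function(structure, file) {
  a <- structure$atoms
  keep <- intersect(c("chain", "resno", "resname", "atom", "type", "radius",
                      "sasa_u", "sasa_c", "dsasa", "is_surface",
                      "is_predictable"), names(a))
  utils::write.table(a[, keep], file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# Apply a rigid motion (rotation matrix R, then translation t) to a structure.
# Exported because the invariance of SASA, knowledge bases, density maps and
# features under rigid motion is part of the package's contract.

#' Rigidly transform a structure
#' @param structure a `ppi_structure`.
#' @param R 3x3 rotation matrix (default identity).
#' @param t length-3 translation (default 0).
#' @return the transformed structure.
#' @export
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  xyz <- coords(structure) %*% t(R)
  structure$atoms$x <- xyz[, 1] + t[1]
  structure$atoms$y <- xyz[, 2] + t[2]
  structure$atoms$z <- xyz[, 3] + t[3]
  structure
}

#' Random rotation matrix
#' @param seed optional integer seed for reproducibility.
#' @return a 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
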