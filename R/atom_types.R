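#' Heavy-atom chemical types for the 20 standard amino acids
#'
#' The pipeline groups protein heavy atoms into 30 chemical classes by
#' element, hybridisation and residue context, plus type 31 for crystal
#' water oxygen. One classifier is trained per protein atom type (1-30);
#' the 31 types also index the interacting-partner dimension of the
#' knowledge base and of the probability density maps.
#'
#' @return A list with components
#'   \describe{
#'     \item{types}{data.frame with columns `type`, `name`, `radius`
#'       (van der Waals radius, Angstrom) and `description`.}
#'     \item{map}{data.frame with columns `resname`, `atom`, `type`
#'       mapping each (residue, heavy atom) pair to its type ID.}
#'   }
#' @export
atom_type_table <- function() {
  types <- data.frame(
    type = 1:31,
    name = c("NH1", "C", "CH1E", "O", "CH0", "CH1S", "CH2E", "CH3E",
             "CR1E", "OH1", "OC", "OS", "CH2G", "CH2P", "NH1S", "NC2",
             "NH2", "CR1W", "CY2", "SC", "CF", "SM", "CY", "CW",
             "CRHH", "NH3", "CR1H", "C5", "N", "C5W", "HOH"),
    radius = c(1.65, 1.76, 1.87, 1.40, 1.76, 1.87, 1.87, 1.87,
               1.76, 1.40, 1.40, 1.40, 1.87, 1.87, 1.65, 1.65,
               1.65, 1.76, 1.76, 1.85, 1.76, 1.85, 1.76, 1.76,
               1.76, 1.50, 1.76, 1.76, 1.65, 1.76, 1.40),
    description = c(
      "Backbone NH", "Backbone C", "Backbone CA (exc. Gly)", "Backbone O",
      "Trigonal C with no H (Arg CZ, Asn/Asp CG, Gln/Glu CD)",
      "Sidechain CH1 (Ile/Thr/Val CB, Leu CG)",
      "Tetrahedral CH2 (all CB not otherwise assigned)",
      "Tetrahedral CH3", "Aromatic CH", "Alcohol OH", "Carboxyl O",
      "Sidechain carbonyl O (Asn OD1, Gln OE1)", "Gly CA", "Pro CB/CG/CD",
      "Sidechain NH (Arg NE, His ND1/NE2, Trp NE1)", "Arg NH1/NH2",
      "Amide NH2 (Asn ND2, Gln NE2)", "Trp CZ2/CH2", "Tyr CZ", "Cys S",
      "Phe CG", "Met S", "Tyr CG", "Trp CD2/CE2", "His CE1", "Lys NZ",
      "His CD2", "His CG", "Pro N", "Trp CG", "Water"),
    stringsAsFactors = FALSE
  )

  # Sidechain assignments per residue.  Backbone atoms are added below for
  # all residues (N/CA/C/O), with Gly CA and Pro N as the two exceptions.
  # Ala CB is a tetrahedral CH3 and is typed CH3E accordingly.
  side <- list(
    ALA = c(CB = 8),
    ARG = c(CB = 7, CG = 7, CD = 7, NE = 15, CZ = 5, NH1 = 16, NH2 = 16),
    ASN = c(CB = 7, CG = 5, OD1 = 12, ND2 = 17),
    ASP = c(CB = 7, CG = 5, OD1 = 11, OD2 = 11),
    CYS = c(CB = 7, SG = 20),
    GLN = c(CB = 7, CG = 7, CD = 5, OE1 = 12, NE2 = 17),
    GLU = c(CB = 7, CG = 7, CD = 5, OE1 = 11, OE2 = 11),
    GLY = c(),
    HIS = c(CB = 7, CG = 28, ND1 = 15, CD2 = 27, CE1 = 25, NE2 = 15),
    ILE = c(CB = 6, CG1 = 7, CG2 = 8, CD1 = 8),
    LEU = c(CB = 7, CG = 6, CD1 = 8, CD2 = 8),
    LYS = c(CB = 7, CG = 7, CD = 7, CE = 7, NZ = 26),
    MET = c(CB = 7, CG = 7, SD = 22, CE = 8),
    PHE = c(CB = 7, CG = 21, CD1 = 9, CD2 = 9, CE1 = 9, CE2 = 9, CZ = 9),
    PRO = c(CB = 14, CG = 14, CD = 14),
    SER = c(CB = 7, OG = 10),
    THR = c(CB = 6, OG1 = 10, CG2 = 8),
    TRP = c(CB = 7, CG = 30, CD1 = 9, CD2 = 24, NE1 = 15, CE2 = 24,
            CE3 = 9, CZ2 = 18, CZ3 = 9, CH2 = 18),
    TYR = c(CB = 7, CG = 23, CD1 = 9, CD2 = 9, CE1 = 9, CE2 = 9,
            CZ = 19, OH = 10),
    VAL = c(CB = 6, CG1 = 8, CG2 = 8)
  )

  rows <- lapply(names(side), function(rn) {
    bb <- c(N = if (rn == "PRO") 29L else 1L,
            CA = if (rn == "GLY") 13L else 3L,
            C = 2L, O = 4L)
    atoms <- c(bb, side[[rn]])
    data.frame(resname = rn, atom = names(atoms),
               type = as.integer(atoms), stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  map <- rbind(map, data.frame(resname = "HOH", atom = "O", type = 31L,
                               stringsAsFactors = FALSE))
  list(types = types, map = map)
}

#' Assign atom types and van der Waals radii to a structure
#'
#' Each retained heavy atom receives a type ID (1-31) and radius from the
#' typing table.  Atoms with no table entry (non-standard residues,
#' terminal OXT, ions) are flagged untyped with a warning and are excluded
#' from prediction downstream; they are never silently typed.
#'
#' @param structure a `ppi_structure` from [parse_structure()].
#' @param table typing table from [atom_type_table()].
#' @return the structure with `type` and `radius` columns filled.
#' @export
assign_atom_types <- function(structure, table = atom_type_table()) {
  stopifnot(inherits(structure, "ppi_structure"))
  at <- structure$atoms
  key <- paste(at$resname, at$atom)
  mkey <- paste(table$map$resname, table$map$atom)
  idx <- match(key, mkey)
  at$type <- table$map$type[idx]
  at$radius <- table$types$radius[at$type]
  if (anyNA(at$type)) {
    bad <- unique(key[is.na(at$type)])
    warning(sprintf("%d atom name(s) without a type entry left untyped: %s",
                    length(bad), paste(utils::head(bad, 8), collapse = ", ")))
  }
  structure$atoms <- at
  structure
}
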