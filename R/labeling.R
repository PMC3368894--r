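#' Label PPI-site atoms by buried surface area
#'
#' For every surface atom of the unbound structure, the fractional loss of
#' solvent-accessible surface area upon complex formation is
#' dSASA = (SASA_u - SASA_c) / SASA_u, clipped to \[0, 1\]; an atom is a PPI
#' site atom when dSASA > 0.  Non-surface atoms receive no label.
#'
#' @param unbound the query chain(s) alone, typed.
#' @param complexed the same atoms inside the complex (same chain /
#'   residue number / atom name keys), plus the partner atoms, typed.
#' @param probe,points SASA quadrature settings (see [compute_sasa()]).
#' @return the unbound structure with `sasa_u`, `sasa_c`, `dsasa`,
#'   `is_surface` and `is_ppi` columns filled.
#' @export
label_ppi_atoms <- function(unbound, complexed, probe = 1.4, points = 960) {
  ukey <- with(unbound$atoms, paste(chain, resno, atom))
  ckey <- with(complexed$atoms, paste(chain, resno, atom))
  miss <- setdiff(ukey, ckey)
  if (length(miss))
    stop("atoms of the unbound structure missing from the complex: ",
         paste(utils::head(miss, 5), collapse = "; "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5))
  if (anyNA(unbound$atoms$sasa_u))
    unbound$atoms$sasa_u <- compute_sasa(unbound, probe, points)
  sasa_all <- compute_sasa(complexed, probe, points)
  unbound$atoms$sasa_c <- sasa_all[match(ukey, ckey)]
  u <- unbound$atoms$sasa_u
  cc <- unbound$atoms$sasa_c
  ds <- ifelse(u > 0, pmin(1, pmax(0, (u - cc) / u)), NA_real_)
  unbound$atoms$dsasa <- ds
  unbound$atoms$is_surface <- u > 0
  unbound$atoms$is_ppi <- !is.na(ds) & ds > 0
  unbound
}

#' Select the atoms eligible for prediction
#'
#' Predictable atoms are surface atoms (SASA_u > 0) of protein atom types
#' 1-30 belonging to residues with complete phi and psi angles; atoms of
#' chain termini, chain breaks and untyped residues are excluded.
#'
#' @param structure a typed structure with SASA computed.
#' @return the structure with the logical `is_predictable` column filled.
#' @export
select_prediction_atoms <- function(structure) {
  a <- structure$atoms
  if (anyNA(a$sasa_u) && nrow(a))
    stop("SASA not computed; run add_sasa() first")
  pp <- phipsi_complete(structure)
  ok <- pp$phipsi_ok[match(paste(a$chain, a$resno), paste(pp$chain, pp$resno))]
  a$is_predictable <- !is.na(a$type) & a$type >= 1L & a$type <= 30L &
    a$sasa_u > 0 & ok
  structure$atoms <- a
  structure
}
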