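#' Interaction filter matrix over the 31 atom types
#'
#' Non-interacting atom-type pairs are eliminated from knowledge-base
#' construction with a 31x31 filter: a pair is admitted when its matrix
#' value is below the threshold (default -0.1).
#'
#' @param values 31x31 numeric matrix keyed by atom type.
#' @param threshold admission threshold; pair admitted iff value < threshold.
#' @return a `ppi_filter` object.
#' @export
filter_matrix <- function(values, threshold = -0.1) {
  values <- as.matrix(values)
  if (nrow(values) != 31L || ncol(values) != 31L || !is.numeric(values))
    stop("filter matrix must be a numeric 31x31 table")
  if (max(abs(values - t(values))) > 1e-9) {
    warning("asymmetric filter matrix symmetrized by pairwise minimum")
    values <- pmin(values, t(values))
  }
  dimnames(values) <- list(1:31, 1:31)
  structure(list(values = values, threshold = threshold),
            class = "ppi_filter")
}

#' Read a filter matrix from TSV
#'
#' @param file path to a 31x31 numeric TSV (optionally with header row and
#'   row-name column).
#' @param threshold admission threshold (default -0.1).
#' @return a `ppi_filter`.
#' @export
load_filter_matrix <- function(file, threshold = -0.1) {
  raw <- utils::read.table(file, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  # tolerate a header row / row-name column of type labels
  if (!is.numeric(raw[[1]]) || nrow(raw) == 32L) {
    raw <- utils::read.table(file, sep = "\t", header = TRUE,
                             row.names = 1, stringsAsFactors = FALSE)
  }
  m <- suppressWarnings(as.matrix(raw))
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric entries in filter matrix file: ", file)
  filter_matrix(m, threshold)
}

#' Admission predicate of a filter
#'
#' @param filter a `ppi_filter`.
#' @param type_a,type_b atom type IDs (1-31), vectorised.
#' @return logical: TRUE where the pair is admitted.
#' @export
filter_admits <- function(filter, type_a, type_b) {
  filter$values[cbind(type_a, type_b)] < filter$threshold
}

#' Synthetic stand-in interaction filter
#'
#' The published filter table is distributed as supplementary data and is
#' not bundled here; this constructor builds a synthetic replacement from
#' simple chemistry, following the filter's stated purpose of keeping the
#' density maps high in information content and low in noise from
#' irrelevant interactions.  Admitted (value -0.5): hydrophobic packing
#' among side-chain aliphatic/aromatic carbons and sulfur (backbone
#' carbonyl C, C-alpha and Gly C-alpha are excluded -- their surfaces are
#' dominated by the flanking amide dipoles, so their incidental carbon
#' contacts carry little interaction information); donor-acceptor hydrogen
#' bonds (N donors with O acceptors, hydroxyl with any O); water with
#' polar atoms.  Every other pair (like-polarity N-N/O-O, polar-apolar
#' mismatches, water-carbon, backbone-carbon packing) is rejected
#' (value 0).  The admission rule (value < -0.1) matches the published
#' convention.
#'
#' @param threshold admission threshold (default -0.1).
#' @return a `ppi_filter` labelled as synthetic in its metadata.
#' @export
synthetic_filter_matrix <- function(threshold = -0.1) {
  side_carbon <- c(6, 7, 8, 9, 14, 18, 19, 21, 23, 24, 25, 27, 28, 30)
  n_don <- c(1, 15, 16, 17, 26, 29)
  o_acc <- c(4, 10, 11, 12)
  hydroxyl <- 10
  sulfur <- c(20, 22)
  water <- 31
  v <- matrix(0, 31, 31)
  admit <- function(a, b) {
    v[a, b] <<- -0.5
    v[b, a] <<- -0.5
  }
  admit(side_carbon, side_carbon)
  admit(n_don, o_acc)
  admit(hydroxyl, o_acc)
  admit(sulfur, c(side_carbon, sulfur))
  admit(water, c(n_don, o_acc))
  f <- filter_matrix(v, threshold)
  f$synthetic <- TRUE
  f
}

#' Write a filter matrix as TSV
#' @param filter a `ppi_filter`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_filter_matrix <- function(filter, file) {
  utils::write.table(filter$values, file, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(file)
}
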