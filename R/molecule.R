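#' Construct a molecule
#'
#' A `qsar_mol` is a light container for a (possibly pseudo-) small molecule:
#' an ordered atom table with 3D coordinates in Angstrom, partial charges in
#' elementary charge units, and per-atom property weights used by the
#' similarity fields (hydrophobic, hydrogen-bond donor, hydrogen-bond
#' acceptor). `skeleton` marks the atoms forming the common scaffold shared
#' across a congeneric series; alignment and the synthetic generator rely on
#' it.
#'
#' @param id compound identifier (coerced to character).
#' @param elements character vector of chemical symbols.
#' @param coords numeric n x 3 matrix of coordinates (Angstrom).
#' @param charge partial charges (e); recycled scalar allowed.
#' @param hydrophobic_w,donor_w,acceptor_w per-atom property weights
#'   (dimensionless); recycled scalars allowed.
#' @param bonds optional integer m x 2 matrix of 1-based atom index pairs.
#' @param skeleton integer indices of common-skeleton atoms (unique, valid).
#' @return an object of class `qsar_mol`.
#' @export
molecule <- function(id, elements, coords, charge = 0,
                     hydrophobic_w = 0, donor_w = 0, acceptor_w = 0,
                     bonds = NULL, skeleton = integer()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (n < 1L) stop("molecule must have at least one atom")
  if (length(elements) != n) stop("length(elements) must match nrow(coords)")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  atoms <- data.frame(
    element = as.character(elements),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    charge = rep_len(as.numeric(charge), n),
    hydrophobic_w = rep_len(as.numeric(hydrophobic_w), n),
    donor_w = rep_len(as.numeric(donor_w), n),
    acceptor_w = rep_len(as.numeric(acceptor_w), n),
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(as.matrix(atoms[, -1])))) {
    stop("charges and property weights must be finite")
  }
  skeleton <- as.integer(skeleton)
  if (anyDuplicated(skeleton) || any(skeleton < 1L | skeleton > n)) {
    stop("skeleton indices must be unique and in 1..n_atoms")
  }
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 2L)
    if (any(bonds < 1L | bonds > n)) stop("bond indices out of range")
  }
  structure(
    list(id = as.character(id), atoms = atoms, bonds = bonds,
         skeleton = skeleton),
    class = "qsar_mol"
  )
}

#' @export
print.qsar_mol <- function(x, ...) {
  cat(sprintf("<qsar_mol %s: %d atoms, %d skeleton, net charge %+0.4f e>\n",
              x$id, nrow(x$atoms), length(x$skeleton),
              sum(x$atoms$charge)))
  invisible(x)
}

#' Atom coordinates of a molecule
#'
#' @param mol a `qsar_mol`.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

`coords<-` <- function(mol, value) {
  stopifnot(nrow(value) == nrow(mol$atoms), ncol(value) == 3L)
  mol$atoms$x <- value[, 1]
  mol$atoms$y <- value[, 2]
  mol$atoms$z <- value[, 3]
  mol
}
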