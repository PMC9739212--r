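#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' mapped atom pairs (mobile onto reference), via SVD of the cross
#' covariance with the usual determinant sign correction, so a reflection
#' is never returned even for near-mirror inputs.
#'
#' @param mobile_coords,ref_coords numeric n x 3 coordinate matrices.
#' @param atom_map optional integer 2-column matrix mapping
#'   `mobile_coords` rows (col 1) to `ref_coords` rows (col 2); default
#'   the identity map (equal row counts required).
#' @return list of class `qsar_alignment`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3, Angstrom), `skeleton_rmsd` (Angstrom). The
#'   fitted placement of a coordinate matrix `X` is
#'   `X %*% t(rotation) + translation` (rows as points).
#' @export
kabsch_superpose <- function(mobile_coords, ref_coords, atom_map = NULL) {
  mobile_coords <- as.matrix(mobile_coords)
  ref_coords <- as.matrix(ref_coords)
  if (is.null(atom_map)) {
    if (nrow(mobile_coords) != nrow(ref_coords)) {
      stop("equal atom counts required without an explicit atom_map")
    }
    atom_map <- cbind(seq_len(nrow(mobile_coords)), seq_len(nrow(ref_coords)))
  }
  A <- mobile_coords[atom_map[, 1], , drop = FALSE]
  B <- ref_coords[atom_map[, 2], , drop = FALSE]
  if (nrow(A) < 3L) stop("need at least 3 mapped atom pairs")
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  # collinearity check: centered points must span a plane
  if (sum(svd(A0)$d > 1e-8) < 2L) {
    stop("mapped atoms are collinear or coincident; superposition is degenerate")
  }
  H <- crossprod(A0, B0)                 # 3 x 3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- as.numeric(cb - R %*% ca)
  fitted <- A %*% t(R) + matrix(translation, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = translation,
                 skeleton_rmsd = rmsd),
            class = "qsar_alignment")
}

#' Apply a rigid transform to a molecule
#'
#' @param mol a [molecule()].
#' @param alignment a `qsar_alignment` from [kabsch_superpose()].
#' @return the molecule with transformed coordinates.
#' @export
transform_molecule <- function(mol, alignment) {
  xyz <- coords(mol)
  new_xyz <- xyz %*% t(alignment$rotation) +
    matrix(alignment$translation, nrow(xyz), 3, byrow = TRUE)
  coords(mol) <- new_xyz
  mol
}

#' Align a congeneric series onto a template
#'
#' Superposes each molecule's common-skeleton atoms onto the template's
#' skeleton (index-to-index, so skeleton vectors must have equal length and
#' order across the series) and applies the resulting rigid transform to
#' all atoms. The template itself is returned unchanged. By 3D-QSAR
#' convention the template is the most active compound.
#'
#' @param molecules list of [molecule()] objects with `skeleton` set.
#' @param template_id id of the template molecule.
#' @return list of aligned molecules, same order; each non-template
#'   molecule carries a `skeleton_rmsd` attribute.
#' @export
align_set <- function(molecules, template_id) {
  ids <- vapply(molecules, `[[`, character(1), "id")
  ti <- match(as.character(template_id), ids)
  if (is.na(ti)) stop("template id not found: ", template_id)
  template <- molecules[[ti]]
  if (length(template$skeleton) < 3L) {
    stop("template ", template_id, " needs >= 3 skeleton atoms")
  }
  ref <- coords(template)[template$skeleton, , drop = FALSE]
  lapply(molecules, function(m) {
    if (m$id == template$id) return(m)
    if (length(m$skeleton) == 0L) {
      stop("molecule ", m$id, " has no skeleton indices")
    }
    if (length(m$skeleton) != length(template$skeleton)) {
      stop("molecule ", m$id, ": skeleton length differs from template")
    }
    mob <- coords(m)[m$skeleton, , drop = FALSE]
    fit <- kabsch_superpose(mob, ref)
    out <- transform_molecule(m, fit)
    attr(out, "skeleton_rmsd") <- fit$skeleton_rmsd
    out
  })
}
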