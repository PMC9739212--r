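#' Convert IC50 in micromolar to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the half-maximal inhibitory
#' concentration in mol/L. With IC50 given in micromolar this is
#' `6 - log10(ic50_uM)`: an IC50 of 1 uM maps to pIC50 6, and a ten-fold
#' gain in potency adds one pIC50 unit.
#'
#' @param ic50_uM positive IC50 value(s), micromolar.
#' @param digits optional number of decimals to round to (e.g. 5 for
#'   report-style tables); `NULL` leaves full precision.
#' @return pIC50 value(s), dimensionless.
#' @seealso [pic50_to_ic50()]
#' @examples
#' ic50_to_pic50(0.54)    # 6.267606
#' ic50_to_pic50(1)       # 6
#' @export
ic50_to_pic50 <- function(ic50_uM, digits = NULL) {
  ic50_uM <- as.numeric(ic50_uM)
  if (any(!is.finite(ic50_uM)) || any(ic50_uM <= 0)) {
    stop("ic50_uM must be finite and > 0")
  }
  p <- 6 - log10(ic50_uM)
  if (!is.null(digits)) p <- round(p, digits)
  p
}

#' Convert pIC50 back to IC50 in micromolar
#'
#' @param pic50 pIC50 value(s).
#' @return IC50 in micromolar.
#' @export
pic50_to_ic50 <- function(pic50) {
  10^(6 - as.numeric(pic50))
}

#' Read an activity table
#'
#' Expects a CSV/TSV with header columns `id`, and at least one of
#' `ic50_uM` / `pic50`; an optional `role` column marks each compound
#' `training` or `test`. Missing pIC50 values are filled from IC50; when
#' both are present they must agree to 1e-4 (guards against unit slips in
#' hand-entered tables).
#'
#' @param path file path; delimiter inferred from extension (.tsv -> tab).
#' @return data.frame with columns `id`, `ic50_uM`, `pic50`, `role`.
#' @export
read_activities <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (!"id" %in% names(tab)) stop("activity table needs an 'id' column")
  if (!any(c("ic50_uM", "pic50") %in% names(tab))) {
    stop("activity table needs an 'ic50_uM' and/or 'pic50' column")
  }
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id)) {
    stop("duplicate compound ids: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  if (is.null(tab$ic50_uM)) tab$ic50_uM <- NA_real_
  if (is.null(tab$pic50)) tab$pic50 <- NA_real_
  both <- !is.na(tab$ic50_uM) & !is.na(tab$pic50)
  if (any(both)) {
    delta <- abs(tab$pic50[both] - ic50_to_pic50(tab$ic50_uM[both]))
    if (any(delta > 1e-4)) {
      bad <- tab$id[both][delta > 1e-4]
      stop("inconsistent IC50/pIC50 pairs for: ", paste(bad, collapse = ", "))
    }
  }
  fill <- is.na(tab$pic50) & !is.na(tab$ic50_uM)
  tab$pic50[fill] <- ic50_to_pic50(tab$ic50_uM[fill])
  back <- is.na(tab$ic50_uM) & !is.na(tab$pic50)
  tab$ic50_uM[back] <- pic50_to_ic50(tab$pic50[back])
  if (any(is.na(tab$pic50))) {
    stop("activity missing for: ", paste(tab$id[is.na(tab$pic50)], collapse = ", "))
  }
  if (is.null(tab$role)) tab$role <- "training"
  tab$role[is.na(tab$role) | tab$role == ""] <- "training"
  if (!all(tab$role %in% c("training", "test"))) {
    stop("role must be 'training' or 'test'")
  }
  tab[, c("id", "ic50_uM", "pic50", "role")]
}

#' Read aligned structures plus an activity table
#'
#' Structures come from an SDF (V2000, parsed with ChemmineR) or a TRIPOS
#' MOL2 file (parsed internally; partial charges are read when present).
#' Every structure must have an activity row and vice versa.
#'
#' @param structure_path SDF or MOL2 file.
#' @param activity_path activity CSV/TSV (see [read_activities()]).
#' @return list with `molecules` (list of [molecule()]) and `records`
#'   (activity data.frame, same order as `molecules`).
#' @export
read_dataset <- function(structure_path, activity_path) {
  mols <- if (grepl("\\.mol2$", structure_path, ignore.case = TRUE)) {
    read_mol2(structure_path)
  } else {
    read_sdf(structure_path)
  }
  if (length(mols) == 0L) stop("no molecules in ", structure_path)
  rec <- read_activities(activity_path)
  mol_ids <- vapply(mols, `[[`, character(1), "id")
  if (anyDuplicated(mol_ids)) {
    stop("duplicate molecule ids in structure file")
  }
  missing_struct <- setdiff(rec$id, mol_ids)
  if (length(missing_struct)) {
    stop("activity rows without structures: ",
         paste(missing_struct, collapse = ", "))
  }
  missing_act <- setdiff(mol_ids, rec$id)
  if (length(missing_act)) {
    stop("structures without activity rows: ",
         paste(missing_act, collapse = ", "))
  }
  rec <- rec[match(mol_ids, rec$id), ]
  rownames(rec) <- NULL
  list(molecules = mols, records = rec)
}

#' Read molecules from an SDF (V2000) file
#'
#' @param path SDF file path.
#' @return list of [molecule()] objects (charges and weights zero; assign
#'   with [assign_peoe_charges()] / [assign_property_weights()]).
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- ChemmineR::read.SDFset(path)
  if (length(set) == 0L) stop("empty structure file: ", path)
  lapply(seq_along(set), function(i) {
    sdf <- set[[i]]
    ab <- ChemmineR::atomblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (nrow(bb) > 0) bb[, 1:2, drop = FALSE] else NULL
    molecule(id = ChemmineR::sdfid(sdf), elements = el,
             coords = ab[, 1:3, drop = FALSE], bonds = bonds)
  })
}

#' Write molecules to an SDF (V2000) file
#'
#' Partial charges and property weights are not representable in V2000 and
#' are dropped; use MOL2 round trips when charges must survive on disk.
#'
#' @param molecules list of [molecule()] objects.
#' @param path output path.
#' @importClassesFrom ChemmineR SDF SDFset
#' @export
write_sdf <- function(molecules, path) {
  sdfs <- lapply(molecules, function(m) {
    xyz <- coords(m)
    n <- nrow(xyz)
    ab <- cbind(xyz, matrix(0, n, 12))
    rownames(ab) <- paste(m$atoms$element, seq_len(n), sep = "_")
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
    bonds <- m$bonds
    if (is.null(bonds)) bonds <- matrix(integer(), 0, 2)
    bb <- cbind(bonds, matrix(1L, nrow(bonds), 1), matrix(0L, nrow(bonds), 1))
    colnames(bb) <- c("C1", "C2", "C3", "C4")
    rownames(bb) <- as.character(seq_len(nrow(bb)))
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bb))
    methods::new("SDF",
                 header = c(Molecule_Name = m$id, Source = "qsarfield",
                            Comment = "", Counts_Line = counts),
                 atomblock = ab, bondblock = bb, datablock = character())
  })
  ids <- vapply(molecules, `[[`, character(1), "id")
  set <- methods::new("SDFset", SDF = sdfs, ID = ids)
  ChemmineR::write.SDF(set, path)
  invisible(path)
}

# Minimal TRIPOS MOL2 reader: MOLECULE/ATOM/BOND records, one or more
# molecules per file; column 9 of ATOM (when present) is the partial charge.
#' Read molecules from a TRIPOS MOL2 file
#'
#' @param path MOL2 file path.
#' @return list of [molecule()] objects with partial charges taken from the
#'   file when present.
#' @export
read_mol2 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0L) stop("no MOLECULE record in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    block <- lines[starts[k]:ends[k]]
    id <- trimws(block[2])
    atom_at <- grep("^@<TRIPOS>ATOM", block)
    if (length(atom_at) != 1L) stop("molecule ", id, ": missing ATOM record")
    sect_ends <- c(grep("^@<TRIPOS>", block), length(block) + 1L)
    atom_end <- min(sect_ends[sect_ends > atom_at]) - 1L
    atom_lines <- block[(atom_at + 1L):atom_end]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    fields <- strsplit(trimws(atom_lines), "[[:space:]]+")
    el <- vapply(fields, function(f) sub("\\..*$", "", f[6]), character(1))
    xyz <- t(vapply(fields, function(f) as.numeric(f[3:5]), numeric(3)))
    q <- vapply(fields, function(f) {
      if (length(f) >= 9) as.numeric(f[9]) else 0
    }, numeric(1))
    bonds <- NULL
    bond_at <- grep("^@<TRIPOS>BOND", block)
    if (length(bond_at) == 1L) {
      bond_end <- min(sect_ends[sect_ends > bond_at]) - 1L
      if (bond_end > bond_at) {
        bl <- block[(bond_at + 1L):bond_end]
        bl <- bl[nzchar(trimws(bl))]
        bf <- strsplit(trimws(bl), "[[:space:]]+")
        bonds <- t(vapply(bf, function(f) as.integer(f[2:3]), integer(2)))
      }
    }
    molecule(id = id, elements = el, coords = xyz, charge = q, bonds = bonds)
  })
}
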