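# Bondi van der Waals radii (Angstrom) and Tripos-style atomic well depths
# (kcal/mol) used by the Lennard-Jones probe energies and the r^3 steric
# similarity weights.
.vdw_radius <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 Cl = 1.75, Br = 1.85, I = 1.98, S = 1.80, P = 1.80)
.well_depth <- c(H = 0.042, C = 0.107, N = 0.095, O = 0.116, F = 0.109,
                 Cl = 0.314, Br = 0.434, I = 0.623, S = 0.314, P = 0.314)

# Coulomb constant in kcal A mol^-1 e^-2
.coulomb_k <- 332.0637

#' Default CoMFA/CoMSIA probe
#'
#' The conventional sp3-carbon probe: vdW radius 1.70 A, well depth 0.107
#' kcal/mol, charge +1 e; unit weights for every similarity property and a
#' Gaussian attenuation factor alpha of 0.3 per square Angstrom.
#'
#' @param vdw_radius,well_depth,charge Lennard-Jones/Coulomb probe
#'   parameters (Angstrom, kcal/mol, e).
#' @param hydrophobic_w,donor_w,acceptor_w similarity probe weights.
#' @param attenuation_alpha Gaussian attenuation (1/A^2).
#' @return list of class `qsar_probe`.
#' @export
default_probe <- function(vdw_radius = 1.70, well_depth = 0.107, charge = 1.0,
                          hydrophobic_w = 1, donor_w = 1, acceptor_w = 1,
                          attenuation_alpha = 0.3) {
  stopifnot(vdw_radius > 0, well_depth > 0, attenuation_alpha > 0)
  structure(list(vdw_radius = vdw_radius, well_depth = well_depth,
                 charge = charge, hydrophobic_w = hydrophobic_w,
                 donor_w = donor_w, acceptor_w = acceptor_w,
                 attenuation_alpha = attenuation_alpha),
            class = "qsar_probe")
}

#' Build a rectangular field grid around an aligned set
#'
#' The axis-aligned bounding box of all atoms, extended by `margin` on
#' every side and discretized at `spacing`; node k along an axis sits at
#' `origin + k * spacing`. Nodes are linearized x-fastest (x varies
#' quickest, then y, then z) throughout the package.
#'
#' @param molecules list of aligned [molecule()] objects.
#' @param spacing lattice spacing (Angstrom), default 2.
#' @param margin box extension beyond the atoms (Angstrom), default 4.
#' @return list of class `qsar_grid`: `origin`, `spacing`, `dims`.
#' @export
make_grid <- function(molecules, spacing = 2.0, margin = 4.0) {
  if (length(molecules) == 0L) stop("empty molecule set")
  if (spacing <= 0) stop("spacing must be > 0")
  if (margin < 0) stop("margin must be >= 0")
  all_xyz <- do.call(rbind, lapply(molecules, coords))
  lo <- apply(all_xyz, 2, min) - margin
  hi <- apply(all_xyz, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  structure(list(origin = lo, spacing = spacing, dims = dims),
            class = "qsar_grid")
}

#' Grid node coordinates
#'
#' @param grid a `qsar_grid`.
#' @return numeric n_nodes x 3 matrix in x-fastest order.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(a) {
    grid$origin[a] + grid$spacing * (seq_len(grid$dims[a]) - 1L)
  })
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

#' @export
print.qsar_grid <- function(x, ...) {
  cat(sprintf("<qsar_grid %dx%dx%d, spacing %.2f A, origin (%.2f, %.2f, %.2f)>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# node-to-atom squared distances: n_nodes x n_atoms
.dist2 <- function(nodes, xyz) {
  outer(rowSums(nodes^2), rowSums(xyz^2), `+`) - 2 * nodes %*% t(xyz)
}

#' CoMFA probe energies on a grid
#'
#' Steric: Lennard-Jones 12-6 energy of the probe at each node,
#' `sum_i eps_i [ (rm_i/r)^12 - 2 (rm_i/r)^6 ]` with `rm_i` the sum of
#' probe and atom vdW radii and `eps_i` the geometric-mean well depth,
#' truncated at +30 kcal/mol. Electrostatic: Coulomb energy
#' `332.0637 q_i q_probe / (eps(r) r)` with distance-dependent dielectric
#' `eps(r) = r`, truncated to [-30, +30]; nodes where the steric energy is
#' at truncation (inside the molecule) are flagged so the descriptor
#' assembly can replace them by the column mean.
#'
#' @param mol a [molecule()] with charges assigned.
#' @param grid a `qsar_grid`.
#' @param probe a `qsar_probe`.
#' @return list with `steric`, `electrostatic` (kcal/mol, one value per
#'   node) and `clash` (logical, steric truncation hit).
#' @export
comfa_fields <- function(mol, grid, probe = default_probe()) {
  nodes <- grid_points(grid)
  xyz <- coords(mol)
  el <- mol$atoms$element
  ri <- .vdw_radius[el]
  ei <- .well_depth[el]
  if (anyNA(ri)) {
    stop("no vdW parameters for element(s): ",
         paste(unique(el[is.na(ri)]), collapse = ", "))
  }
  d2 <- .dist2(nodes, xyz)
  d2[d2 < 1e-12] <- 1e-12           # node on an atom center: clamp below
  rm2 <- matrix((probe$vdw_radius + ri)^2, nrow(d2), ncol(d2), byrow = TRUE)
  s6 <- (rm2 / d2)^3
  eps <- matrix(sqrt(probe$well_depth * ei), nrow(d2), ncol(d2), byrow = TRUE)
  steric <- rowSums(eps * (s6^2 - 2 * s6))
  clash <- steric >= 30
  steric <- pmin(steric, 30)
  qmat <- matrix(mol$atoms$charge, nrow(d2), ncol(d2), byrow = TRUE)
  elec <- rowSums(.coulomb_k * probe$charge * qmat / d2)  # eps(r) = r
  elec <- pmin(pmax(elec, -30), 30)
  list(steric = steric, electrostatic = elec, clash = clash)
}

#' CoMSIA similarity indices on a grid
#'
#' Gaussian-attenuated similarity between the probe and the molecule,
#' `A_k(node) = -sum_i w_probe_k w_ik exp(-alpha r_i^2)`, for property
#' kinds among steric, electrostatic, hydrophobic, donor and acceptor.
#' Steric atom weights follow the r_vdw^3 convention; electrostatic
#' weights are the partial charges; the remaining kinds use the assigned
#' per-atom property weights.
#'
#' @param mol a [molecule()] with charges/weights assigned.
#' @param grid a `qsar_grid`.
#' @param probe a `qsar_probe` (weights and `attenuation_alpha` used).
#' @param kinds character subset of
#'   `c("steric", "electrostatic", "hydrophobic", "donor", "acceptor")`.
#' @return named list of per-node similarity vectors, one per kind.
#' @export
comsia_fields <- function(mol, grid, probe = default_probe(),
                          kinds = c("steric", "electrostatic", "hydrophobic",
                                    "donor", "acceptor")) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  nodes <- grid_points(grid)
  xyz <- coords(mol)
  el <- mol$atoms$element
  g <- exp(-probe$attenuation_alpha * .dist2(nodes, xyz))
  atom_w <- function(kind) {
    switch(kind,
      steric = {
        ri <- .vdw_radius[el]
        if (anyNA(ri)) stop("no vdW radius for element(s): ",
                            paste(unique(el[is.na(ri)]), collapse = ", "))
        unname(ri^3)
      },
      electrostatic = mol$atoms$charge,
      hydrophobic = mol$atoms$hydrophobic_w,
      donor = mol$atoms$donor_w,
      acceptor = mol$atoms$acceptor_w
    )
  }
  probe_w <- c(steric = 1, electrostatic = probe$charge,
               hydrophobic = probe$hydrophobic_w, donor = probe$donor_w,
               acceptor = probe$acceptor_w)
  out <- lapply(kinds, function(k) {
    as.numeric(-(g %*% atom_w(k)) * probe_w[k])
  })
  names(out) <- kinds
  out
}

#' Compute a field set for a molecule series
#'
#' Evaluates either the CoMFA probe energies (steric + electrostatic) or
#' the CoMSIA similarity indices for every molecule on a shared grid and
#' stacks them into per-kind compound-by-node matrices.
#'
#' @param molecules list of aligned [molecule()] objects.
#' @param grid a `qsar_grid`.
#' @param probe a `qsar_probe`.
#' @param model `"comfa"` or `"comsia"`.
#' @param kinds CoMSIA property kinds (ignored for CoMFA).
#' @return list of class `qsar_fieldset`: `fields` (named list of
#'   matrices), `clash` (matrix or NULL), `grid`, `model`, `ids`.
#' @export
compute_fields <- function(molecules, grid, probe = default_probe(),
                           model = c("comfa", "comsia"),
                           kinds = c("steric", "hydrophobic", "donor",
                                     "acceptor")) {
  model <- match.arg(model)
  ids <- vapply(molecules, `[[`, character(1), "id")
  if (model == "comfa") {
    per <- lapply(molecules, comfa_fields, grid = grid, probe = probe)
    fields <- list(
      steric = do.call(rbind, lapply(per, `[[`, "steric")),
      electrostatic = do.call(rbind, lapply(per, `[[`, "electrostatic"))
    )
    clash <- do.call(rbind, lapply(per, `[[`, "clash"))
  } else {
    per <- lapply(molecules, comsia_fields, grid = grid, probe = probe,
                  kinds = kinds)
    fields <- lapply(stats::setNames(kinds, kinds), function(k) {
      do.call(rbind, lapply(per, `[[`, k))
    })
    clash <- NULL
  }
  fields <- lapply(fields, function(m) {
    rownames(m) <- ids
    m
  })
  structure(list(fields = fields, clash = clash, grid = grid,
                 model = model, ids = ids),
            class = "qsar_fieldset")
}

#' Assemble, filter and scale the descriptor block
#'
#' Concatenates the per-kind field matrices into one compounds-by-columns
#' matrix with column metadata (field kind, grid node). For CoMFA,
#' electrostatic values at sterically clashed nodes are first replaced by
#' the column mean over non-clashed compounds (0 if every compound
#' clashes). Columns whose standard deviation falls below `filter_sigma`
#' are dropped (the minimum-sigma filter; `kept_mask` records the
#' decision). Under `scaling = "comfa_std"` each field's kept sub-block is
#' rescaled so all fields carry equal total column variance, preventing
#' the widest-ranging field from dominating the PLS solution.
#'
#' @param fieldset a `qsar_fieldset` from [compute_fields()].
#' @param filter_sigma minimum column standard deviation (field units).
#' @param scaling `"comfa_std"` (equal per-field variance) or `"none"`.
#' @param ref_rows optional row (compound) indices over which standard
#'   deviations for filtering/scaling are computed - typically the
#'   training set, so filter and scale decisions never see test
#'   compounds; default all rows.
#' @return list of class `field_block`: `matrix` (kept, scaled columns),
#'   `column_meta` (data.frame kind/node for kept columns), `kept_mask`,
#'   `raw_sd` (pre-scaling sd of kept columns over `ref_rows`),
#'   `scale_factors`, `grid`, `kinds`, `n_nodes`, `ids`.
#' @export
build_block <- function(fieldset, filter_sigma = 2.0,
                        scaling = c("comfa_std", "none"),
                        ref_rows = NULL) {
  scaling <- match.arg(scaling)
  kinds <- names(fieldset$fields)
  n_nodes <- ncol(fieldset$fields[[1]])
  if (!all(vapply(fieldset$fields, ncol, integer(1)) == n_nodes)) {
    stop("inconsistent field vector lengths across kinds")
  }
  fields <- fieldset$fields
  if (!is.null(fieldset$clash) && "electrostatic" %in% kinds) {
    e <- fields$electrostatic
    cl <- fieldset$clash
    for (j in which(colSums(cl) > 0L)) {
      ok <- !cl[, j]
      e[!ok, j] <- if (any(ok)) mean(e[ok, j]) else 0
    }
    fields$electrostatic <- e
  }
  X <- do.call(cbind, fields)
  meta <- data.frame(
    kind = rep(kinds, each = n_nodes),
    node = rep(seq_len(n_nodes), length(kinds)),
    stringsAsFactors = FALSE
  )
  if (is.null(ref_rows)) ref_rows <- seq_len(nrow(X))
  sds <- apply(X[ref_rows, , drop = FALSE], 2, stats::sd)
  kept_mask <- sds >= filter_sigma
  if (!any(kept_mask)) stop("all columns removed by the sigma filter")
  Xk <- X[, kept_mask, drop = FALSE]
  meta_k <- meta[kept_mask, , drop = FALSE]
  raw_sd <- sds[kept_mask]
  scale_factors <- stats::setNames(rep(1, length(kinds)), kinds)
  if (scaling == "comfa_std") {
    v_by_kind <- vapply(kinds, function(k) {
      sum(raw_sd[meta_k$kind == k]^2)
    }, numeric(1))
    present <- v_by_kind > 0
    target <- mean(v_by_kind[present])
    scale_factors[present] <- sqrt(target / v_by_kind[present])
    Xk <- Xk * rep(scale_factors[meta_k$kind], each = nrow(Xk))
  }
  rownames(meta_k) <- NULL
  structure(list(matrix = Xk, column_meta = meta_k, kept_mask = kept_mask,
                 raw_sd = unname(raw_sd), scale_factors = scale_factors,
                 grid = fieldset$grid, kinds = kinds, n_nodes = n_nodes,
                 ids = fieldset$ids),
            class = "field_block")
}

#' @export
print.field_block <- function(x, ...) {
  cat(sprintf("<field_block: %d compounds x %d kept columns (of %d), fields: %s>\n",
              nrow(x$matrix), ncol(x$matrix),
              length(x$kept_mask), paste(x$kinds, collapse = ", ")))
  invisible(x)
}
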