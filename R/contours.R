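#' StDev x Coeff volume for one field kind
#'
#' At every kept grid node the value is the product of the training-set
#' standard deviation of that descriptor column and its PLS coefficient,
#' expressed in original (pre-scaling) field units - the product is
#' invariant to the per-field block scaling, since the scale factor
#' cancels between the sd and the coefficient. Filtered (near-constant)
#' columns carry value 0 and are marked in the mask. Positive values mark
#' regions where more of the property favors activity; negative values
#' disfavor it.
#'
#' @param model a `pls_model` fitted on `block`.
#' @param block the `field_block` used for fitting.
#' @param field_kind one of the block's field kinds.
#' @param ncomp component count (default: the model's).
#' @return list of class `volume_map`: `grid`, `values` (one per node,
#'   x-fastest), `mask` (TRUE where a kept column exists), `field_kind`.
#' @export
stdev_coeff_volume <- function(model, block, field_kind, ncomp = NULL) {
  if (!field_kind %in% block$kinds) {
    stop("field kind not in block: ", field_kind)
  }
  if (is.null(ncomp)) ncomp <- model$n_components
  b <- model$coefficients[, ncomp]
  if (length(b) != ncol(block$matrix)) {
    stop("model and block column counts differ")
  }
  sel <- block$column_meta$kind == field_kind
  s <- block$scale_factors[[field_kind]]
  # coef in original units = scaled coef * s; sd in original units = raw_sd
  vals_kept <- block$raw_sd[sel] * (b[sel] * s)
  values <- numeric(block$n_nodes)
  mask <- logical(block$n_nodes)
  nodes <- block$column_meta$node[sel]
  values[nodes] <- vals_kept
  mask[nodes] <- TRUE
  structure(list(grid = block$grid, values = values, mask = mask,
                 field_kind = field_kind),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat(sprintf("<volume_map '%s': %d nodes, %d nonzero, range [%.4g, %.4g]>\n",
              x$field_kind, length(x$values), sum(x$values != 0),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Contribution-based contour levels
#'
#' Orders the nonzero node values ascending and accumulates their absolute
#' values into a cumulative contribution mass. The favored level is the
#' node value at which the cumulative mass first reaches
#' `favored_fraction` of the total (so the isosurface above it encloses
#' the top `1 - favored_fraction` of contribution); the disfavored level
#' is the value at `disfavored_fraction` of the mass. With the
#' conventional 0.8/0.2 fractions this is the usual "80% favored / 20%
#' disfavored contribution" display convention.
#'
#' @param volume a `volume_map`.
#' @param favored_fraction,disfavored_fraction contribution fractions in
#'   (0, 1); favored must be >= disfavored.
#' @return list of class `contour_levels`: `favored_level`,
#'   `disfavored_level`, `favored_fraction`, `disfavored_fraction`.
#' @export
contour_levels <- function(volume, favored_fraction = 0.8,
                           disfavored_fraction = 0.2) {
  stopifnot(favored_fraction > 0, favored_fraction < 1,
            disfavored_fraction > 0, disfavored_fraction < 1,
            favored_fraction >= disfavored_fraction)
  v <- volume$values[volume$values != 0]
  if (length(v) == 0L) stop("all-zero volume; no contour levels")
  v <- sort(v)
  mass <- cumsum(abs(v)) / sum(abs(v))
  level_at <- function(f) v[which(mass >= f - 1e-12)[1]]
  structure(list(favored_level = level_at(favored_fraction),
                 disfavored_level = level_at(disfavored_fraction),
                 favored_fraction = favored_fraction,
                 disfavored_fraction = disfavored_fraction),
            class = "contour_levels")
}

#' Write a volume map as an OpenDX scalar field
#'
#' Standard DX regular-grid scalar field readable by common molecular
#' viewers. DX convention stores the last grid index (z) fastest; the
#' in-memory x-fastest linearization is permuted on write and restored by
#' [read_volume()]; the header comment records this.
#'
#' @param volume a `volume_map`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path) {
  g <- volume$grid
  nx <- g$dims[1]; ny <- g$dims[2]; nz <- g$dims[3]
  # x-fastest (in-memory) -> z-fastest (DX file order)
  arr <- array(volume$values, dim = c(nx, ny, nz))
  vals_zfast <- as.numeric(aperm(arr, c(3, 2, 1)))
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    stop("cannot open for writing: ", path)
  })
  on.exit(close(con))
  writeLines(c(
    sprintf("# qsarfield StDev*Coeff volume, field kind: %s", volume$field_kind),
    "# in-memory node order is x-fastest; values below follow the DX",
    "# convention (z-fastest for counts nx ny nz)",
    sprintf("object 1 class gridpositions counts %d %d %d", nx, ny, nz),
    sprintf("origin %.6f %.6f %.6f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", g$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", g$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", nx, ny, nz),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals_zfast))
  ), con)
  chunks <- split(vals_zfast,
                  (seq_along(vals_zfast) - 1L) %/% 3L)
  writeLines(vapply(chunks, function(ch) {
    paste(sprintf("%.6e", ch), collapse = " ")
  }, character(1)), con)
  writeLines(c(
    'attribute "dep" string "positions"',
    'object "regular positions regular connections" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3'
  ), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_volume()]
#'
#' @param path DX file path.
#' @return a `volume_map` (mask marks nonzero nodes; the original filter
#'   mask is not stored in the DX format).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  grab <- function(pattern) {
    hit <- grep(pattern, lines, value = TRUE)[1]
    if (is.na(hit)) stop("malformed DX file: missing ", pattern)
    as.numeric(strsplit(trimws(sub(pattern, "", hit)), "[[:space:]]+")[[1]])
  }
  dims <- as.integer(grab("^object 1 class gridpositions counts"))
  origin <- grab("^origin")
  deltas <- lines[grep("^delta", lines)]
  spacing <- as.numeric(strsplit(trimws(sub("^delta", "", deltas[1])),
                                 "[[:space:]]+")[[1]][1])
  data_at <- grep("class array .* data follows$", lines)
  n_items <- as.integer(sub(".* items ([0-9]+) data follows$", "\\1",
                            lines[data_at]))
  vals <- numeric(0)
  i <- data_at + 1L
  while (length(vals) < n_items && i <= length(lines)) {
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]),
                                        "[[:space:]]+")[[1]]))
    i <- i + 1L
  }
  if (length(vals) != n_items) stop("truncated DX data section")
  arr <- array(vals, dim = rev(dims))          # z-fastest on file
  values <- as.numeric(aperm(arr, c(3, 2, 1))) # back to x-fastest
  kind <- sub("^.*field kind: ", "", grep("field kind:", lines, value = TRUE)[1])
  if (is.na(kind)) kind <- "unknown"
  grid <- structure(list(origin = origin, spacing = spacing, dims = dims),
                    class = "qsar_grid")
  structure(list(grid = grid, values = values, mask = values != 0,
                 field_kind = kind),
            class = "volume_map")
}
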