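# Gasteiger-Marsili PEOE electronegativity polynomials chi(q) = a + b q + c q^2
# (eV; sp3-level values per element). The cation electronegativity a + b + c
# normalizes the charge transferred per bond; hydrogen uses the conventional
# 20.02 instead of its polynomial value.
.peoe_params <- data.frame(
  element = c("H", "C", "N", "O", "F", "Cl", "Br", "I", "S", "P"),
  a = c(7.17, 7.98, 11.54, 14.18, 14.66, 11.00, 10.08, 9.90, 10.14, 8.90),
  b = c(6.24, 9.18, 10.82, 12.92, 13.85, 9.69, 8.47, 7.96, 9.13, 8.24),
  c = c(-0.56, 1.88, 1.36, 1.39, 2.31, 1.35, 1.16, 0.96, 1.38, 0.96),
  stringsAsFactors = FALSE
)

#' Assign Gasteiger (PEOE) partial charges
#'
#' Iterative partial equalization of orbital electronegativities: in each
#' sweep, every bond transfers charge from the less to the more
#' electronegative atom in proportion to the electronegativity difference,
#' damped by `0.5^k` at sweep `k`, with electronegativities re-evaluated
#' from the current charges via the per-element quadratic chi(q). Charge is
#' conserved exactly (each transfer is antisymmetric), so a molecule started
#' at its net formal charge keeps it.
#'
#' @param mol a [molecule()] with a bond list.
#' @param n_iter number of damped sweeps (default 6; increments beyond that
#'   are below 1e-3 e).
#' @param formal_charges optional per-atom starting charges (default all 0,
#'   i.e. a neutral molecule).
#' @return the molecule with `atoms$charge` replaced.
#' @export
assign_peoe_charges <- function(mol, n_iter = 6L, formal_charges = NULL) {
  if (is.null(mol$bonds) || nrow(mol$bonds) == 0L) {
    stop("molecule ", mol$id, " has no bonds; PEOE needs connectivity")
  }
  el <- mol$atoms$element
  idx <- match(el, .peoe_params$element)
  if (anyNA(idx)) {
    stop("no PEOE parameters for element(s): ",
         paste(unique(el[is.na(idx)]), collapse = ", "))
  }
  a <- .peoe_params$a[idx]
  b <- .peoe_params$b[idx]
  cc <- .peoe_params$c[idx]
  chi_plus <- a + b + cc
  chi_plus[el == "H"] <- 20.02
  q <- if (is.null(formal_charges)) numeric(length(el)) else
    rep_len(as.numeric(formal_charges), length(el))
  bi <- mol$bonds[, 1]
  bj <- mol$bonds[, 2]
  for (k in seq_len(n_iter)) {
    chi <- a + b * q + cc * q^2
    lo <- ifelse(chi[bi] <= chi[bj], bi, bj)   # electron donor (less EN)
    hi <- ifelse(chi[bi] <= chi[bj], bj, bi)
    dq <- (chi[hi] - chi[lo]) / chi_plus[lo] * 0.5^k
    dvec <- numeric(length(q))
    # synchronous update: all transfers computed from start-of-sweep charges
    for (m in seq_along(dq)) {
      dvec[lo[m]] <- dvec[lo[m]] + dq[m]
      dvec[hi[m]] <- dvec[hi[m]] - dq[m]
    }
    q <- q + dvec
  }
  mol$atoms$charge <- q
  mol
}

# Atomic hydrophobicity weights: a published fragmental logP contribution
# scheme collapsed to one weight per element (carbon and halogens
# lipophilic, heteroatoms hydrophilic). Deliberately coarse: the similarity
# fields only need relative per-atom weights, not a logP prediction.
.default_hydrophobic <- c(
  C = 0.5, H = 0.2, N = -0.5, O = -0.6, F = 0.2,
  Cl = 0.5, Br = 0.6, I = 0.8, S = 0.3, P = -0.2
)

#' Default atom-typing rules for property weights
#'
#' @return a list with a per-element `hydrophobic` lookup plus the N/O
#'   valence rules used for donors/acceptors (documented here so callers
#'   can substitute their own table).
#' @export
default_property_rules <- function() {
  list(hydrophobic = .default_hydrophobic,
       donor_elements = c("N", "O"),
       acceptor_elements = c("N", "O"),
       acceptor_max_degree = c(N = 3L, O = 2L))
}

#' Assign hydrophobic / donor / acceptor atom weights
#'
#' Simple valence rules on the heavy atoms: a nitrogen or oxygen carrying at
#' least one bonded hydrogen gets `donor_w = 1`; a nitrogen with at most
#' three connections or any oxygen gets `acceptor_w = 1` (lone pair
#' available); hydrophobic weights come from a per-element lookup. Hydrogens
#' themselves carry no donor/acceptor weight - the heavy atom does.
#'
#' @param mol a [molecule()] with a bond list (needed for H attachment).
#' @param rules rule table, see [default_property_rules()].
#' @return the molecule with `hydrophobic_w`, `donor_w`, `acceptor_w` set.
#' @export
assign_property_weights <- function(mol, rules = default_property_rules()) {
  el <- mol$atoms$element
  hw <- rules$hydrophobic[el]
  if (anyNA(hw)) {
    stop("no property rule for element(s): ",
         paste(unique(el[is.na(hw)]), collapse = ", "))
  }
  n <- length(el)
  degree <- integer(n)
  h_neighbors <- integer(n)
  if (!is.null(mol$bonds) && nrow(mol$bonds) > 0L) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]
      degree[i] <- degree[i] + 1L
      degree[j] <- degree[j] + 1L
      if (el[j] == "H") h_neighbors[i] <- h_neighbors[i] + 1L
      if (el[i] == "H") h_neighbors[j] <- h_neighbors[j] + 1L
    }
  }
  donor <- as.numeric(el %in% rules$donor_elements & h_neighbors > 0L)
  maxdeg <- rules$acceptor_max_degree[el]
  acceptor <- as.numeric(el %in% rules$acceptor_elements &
                           (is.na(maxdeg) | degree <= maxdeg))
  mol$atoms$hydrophobic_w <- unname(hw)
  mol$atoms$donor_w <- donor
  mol$atoms$acceptor_w <- acceptor
  mol
}
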