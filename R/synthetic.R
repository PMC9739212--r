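#' Configuration for the synthetic congeneric series
#'
#' The generator emulates the structure of a congeneric inhibitor series:
#' a rigid common skeleton shared (pre-aligned) by every molecule, with
#' variable substituents grown at fixed attachment sites, and activities
#' produced by a planted linear model on true interaction-field values at
#' chosen grid nodes plus Gaussian noise. Substituent atoms are
#' carbon-like pseudo-atoms whose similarity-field properties are drawn
#' from documented ranges: partial charge U(-0.5, 0.5) e, hydrophobic
#' weight U(0, 1), donor and acceptor flags Bernoulli(0.3) - wide enough
#' to exercise all five similarity kinds.
#'
#' @param n_molecules series size (>= 8); default 40.
#' @param skeleton_size skeleton atom count (>= 6); default 12.
#' @param substituent_sites number of attachment sites; default 2.
#' @param max_substituent_atoms per-site maximum substituent size; default 4.
#' @param effects data.frame with columns `site` (attachment site whose
#'   vicinity carries the effect), `kind` (field kind) and `coef`
#'   (activity units per field unit) defining the planted linear model.
#'   The default plants steric, hydrophobic, donor and acceptor effects
#'   mixing both signs.
#' @param noise_sd Gaussian activity noise (pIC50 units); default 0.3.
#' @param base_activity intercept of the planted model (pIC50); default 6.5.
#' @param training_fraction for the nested-range split; default 0.75.
#' @param spacing,margin grid geometry (Angstrom) for the true fields.
#' @param probe `qsar_probe` used for the true field evaluation.
#' @param seed integer master seed; structure, noise and split use fixed
#'   offsets from it, so the whole set is reproducible from one integer.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_molecules = 40L, skeleton_size = 12L,
                             substituent_sites = 2L,
                             max_substituent_atoms = 4L,
                             effects = NULL, noise_sd = 0.3,
                             base_activity = 6.5,
                             training_fraction = 0.75,
                             spacing = 2.0, margin = 4.0,
                             probe = default_probe(), seed = 1L) {
  if (n_molecules < 8L) stop("n_molecules must be >= 8")
  if (skeleton_size < 6L) stop("skeleton_size must be >= 6")
  if (substituent_sites < 1L) stop("need at least one substituent site")
  if (max_substituent_atoms < 1L) stop("max_substituent_atoms must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(effects)) {
    effects <- data.frame(
      site = c(1L, 1L, 2L, 2L),
      kind = c("steric", "hydrophobic", "donor", "acceptor"),
      coef = c(-0.30, 1.50, 1.20, -1.00),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("site", "kind", "coef") %in% names(effects)))
  if (any(effects$site > substituent_sites)) {
    stop("effect site index exceeds substituent_sites")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 skeleton_size = as.integer(skeleton_size),
                 substituent_sites = as.integer(substituent_sites),
                 max_substituent_atoms = as.integer(max_substituent_atoms),
                 effects = effects, noise_sd = noise_sd,
                 base_activity = base_activity,
                 training_fraction = training_fraction,
                 spacing = spacing, margin = margin, probe = probe,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Deterministic skeleton: a hexagonal carbon ring in the z = 0 plane plus
# a zig-zag chain, identical for every molecule and every seed.
.skeleton_coords <- function(skeleton_size) {
  ang <- (0:5) * pi / 3
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  n_chain <- skeleton_size - 6L
  if (n_chain > 0L) {
    chain <- cbind(1.4 + 1.3 * seq_len(n_chain),
                   0.5 * (seq_len(n_chain) %% 2L), 0)
    rbind(ring, chain)
  } else ring
}

# Attachment sites: evenly spread skeleton atoms; outward direction away
# from the skeleton centroid, tilted out of plane so substituents occupy
# 3D space.
.site_anchors <- function(skel, n_sites) {
  n <- nrow(skel)
  at <- unique(pmax(1L, round(seq(1, n, length.out = n_sites + 2L))))
  at <- at[-c(1L, length(at))]
  while (length(at) < n_sites) at <- c(at, n - length(at))
  at <- at[seq_len(n_sites)]
  ctr <- colMeans(skel)
  lapply(seq_len(n_sites), function(s) {
    dir <- skel[at[s], ] - ctr
    dir[3] <- 0.6 * (-1)^s          # alternate above/below the ring plane
    dir <- dir / sqrt(sum(dir^2))
    list(atom = at[s], dir = dir, anchor = skel[at[s], ] + 1.5 * dir)
  })
}

#' Generate a synthetic congeneric series with planted activities
#'
#' All randomness derives from `config$seed`: structures use the seed
#' itself, activity noise the seed + 1000003, and the training/test split
#' the seed + 2000003, so stages rerun stably. Skeleton coordinates are
#' fixed (the set is born aligned). The activity of molecule i is
#' `base + sum_e coef_e * A_{kind_e}(node_e; molecule i) + N(0, noise_sd)`
#' where A is the similarity field of [comsia_fields()] evaluated on the
#' shared grid - so the planted truth lives in exactly the descriptor
#' space the pipeline reconstructs.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_set`: `molecules` (aligned, with
#'   charges/weights set), `records` (activity table with nested-range
#'   roles), `truth` (grid, probe, effects with grid node indices, planted
#'   field values, base, noise), `config`.
#' @export
generate_set <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  skel <- .skeleton_coords(config$skeleton_size)
  sites <- .site_anchors(skel, config$substituent_sites)
  n <- config$n_molecules
  molecules <- with_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      el <- rep("C", nrow(skel))
      xyz <- skel
      chg <- numeric(nrow(skel))
      hyd <- rep(0.5, nrow(skel))
      don <- numeric(nrow(skel))
      acc <- numeric(nrow(skel))
      bonds <- cbind(1:6, c(2:6, 1))
      if (nrow(skel) > 6L) {
        bonds <- rbind(bonds, cbind(c(1L, seq_len(nrow(skel) - 7L) + 6L),
                                    7:nrow(skel)))
      }
      for (s in seq_along(sites)) {
        k <- sample.int(config$max_substituent_atoms, 1L)
        prev <- sites[[s]]$atom
        for (j in seq_len(k)) {
          pos <- sites[[s]]$anchor + (j - 1L) * 1.2 * sites[[s]]$dir +
            stats::rnorm(3, 0, 0.35)
          xyz <- rbind(xyz, pos)
          el <- c(el, "C")
          chg <- c(chg, stats::runif(1, -0.5, 0.5))
          hyd <- c(hyd, stats::runif(1, 0, 1))
          don <- c(don, as.numeric(stats::runif(1) < 0.3))
          acc <- c(acc, as.numeric(stats::runif(1) < 0.3))
          bonds <- rbind(bonds, c(prev, nrow(xyz)))
          prev <- nrow(xyz)
        }
      }
      molecule(id = sprintf("m%02d", i), elements = el, coords = xyz,
               charge = chg, hydrophobic_w = hyd, donor_w = don,
               acceptor_w = acc, bonds = bonds,
               skeleton = seq_len(nrow(skel)))
    })
  })
  grid <- make_grid(molecules, spacing = config$spacing,
                    margin = config$margin)
  nodes <- grid_points(grid)
  # planted effect nodes: grid node nearest to each site's substituent zone
  eff <- config$effects
  eff$node <- vapply(seq_len(nrow(eff)), function(e) {
    target <- sites[[eff$site[e]]]$anchor + 1.0 * sites[[eff$site[e]]]$dir
    which.min(colSums((t(nodes) - target)^2))
  }, integer(1))
  kinds_needed <- unique(eff$kind)
  field_values <- t(vapply(molecules, function(m) {
    f <- comsia_fields(m, grid, config$probe, kinds = kinds_needed)
    vapply(seq_len(nrow(eff)), function(e) f[[eff$kind[e]]][eff$node[e]],
           numeric(1))
  }, numeric(nrow(eff))))
  if (nrow(eff) == 1L) field_values <- matrix(field_values, ncol = 1L)
  noise <- with_seed(config$seed + 1000003L,
                     stats::rnorm(n, 0, config$noise_sd))
  pic50 <- config$base_activity +
    as.numeric(field_values %*% eff$coef) + noise
  records <- data.frame(
    id = vapply(molecules, `[[`, character(1), "id"),
    ic50_uM = pic50_to_ic50(pic50),
    pic50 = pic50,
    role = "training",
    stringsAsFactors = FALSE
  )
  split <- split_train_test(records,
                            training_fraction = config$training_fraction,
                            seed = config$seed + 2000003L)
  records$role[records$id %in% split$test_ids] <- "test"
  structure(list(molecules = molecules, records = records,
                 truth = list(grid = grid, probe = config$probe,
                              effects = eff, field_values = field_values,
                              base = config$base_activity, noise = noise),
                 config = config),
            class = "synthetic_set")
}

#' @export
print.synthetic_set <- function(x, ...) {
  cat(sprintf("<synthetic_set: %d molecules (%d test), %d planted effects, noise sd %.2f>\n",
              length(x$molecules), sum(x$records$role == "test"),
              nrow(x$truth$effects), x$config$noise_sd))
  invisible(x)
}

#' Check how well the pipeline recovers the planted truth
#'
#' Runs the standard similarity-field pipeline on a synthetic set (or
#' accepts a pre-computed [qsar_pipeline()] result on the truth grid) and
#' reports internal and external predictivity together with effect-node
#' recovery: for each planted effect, the StDev*Coeff value at the true
#' node is compared with the planted coefficient (sign agreement and
#' Pearson correlation across effects).
#'
#' @param synth a `synthetic_set`.
#' @param fit optional `qsar_fit` computed on `synth` with the truth grid.
#' @param ... further arguments to [qsar_pipeline()] when `fit` is NULL.
#' @return list of class `recovery_report`: `q2`, `rpred2`, `effects`
#'   (data.frame with planted and recovered values and `sign_ok`),
#'   `sign_agreement`, `correlation`, `fit`.
#' @export
recovery_check <- function(synth, fit = NULL, ...) {
  stopifnot(inherits(synth, "synthetic_set"))
  if (is.null(fit)) {
    fit <- qsar_pipeline(synth$molecules, synth$records, model = "comsia",
                         kinds = unique(synth$truth$effects$kind),
                         grid = synth$truth$grid, probe = synth$truth$probe,
                         align = FALSE, ...)
  }
  g1 <- fit$block$grid
  g2 <- synth$truth$grid
  if (!isTRUE(all.equal(g1$origin, g2$origin)) ||
      g1$spacing != g2$spacing || !all(g1$dims == g2$dims)) {
    stop("pipeline grid differs from the truth grid")
  }
  eff <- synth$truth$effects
  eff$recovered <- vapply(seq_len(nrow(eff)), function(e) {
    vol <- stdev_coeff_volume(fit$model, fit$block, eff$kind[e])
    vol$values[eff$node[e]]
  }, numeric(1))
  eff$sign_ok <- sign(eff$recovered) == sign(eff$coef) & eff$recovered != 0
  correlation <- if (nrow(eff) >= 3L) stats::cor(eff$coef, eff$recovered)
                 else NA_real_
  structure(list(q2 = fit$cv$q2_onc,
                 rpred2 = fit$external$rpred2,
                 effects = eff,
                 sign_agreement = mean(eff$sign_ok),
                 correlation = correlation,
                 fit = fit),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report: q2 %.3f, Rpred2 %.3f, sign agreement %.0f%%, cor %.3f>\n",
              x$q2, if (is.null(x$rpred2)) NA_real_ else x$rpred2,
              100 * x$sign_agreement, x$correlation))
  invisible(x)
}
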