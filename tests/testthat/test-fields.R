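test_that("grid construction covers the set with the requested margin", {
  single <- molecule("a", "C", rbind(c(0, 0, 0)))
  g <- make_grid(list(single), spacing = 2, margin = 4)
  expect_equal(g$dims, c(5L, 5L, 5L))
  expect_equal(g$origin, c(-4, -4, -4), ignore_attr = TRUE)
  pts <- grid_points(g)
  expect_equal(nrow(pts), 125L)
  expect_equal(range(pts), c(-4, 4))
  # x varies fastest in the linearization
  expect_equal(pts[1:5, 1], seq(-4, 4, by = 2))
  expect_equal(pts[1:5, 2], rep(-4, 5))

  m <- toy_mol()
  g2 <- make_grid(list(m), spacing = 1.5, margin = 3)
  box_lo <- g2$origin
  box_hi <- g2$origin + (g2$dims - 1) * g2$spacing
  xyz <- coords(m)
  expect_true(all(t(xyz) >= box_lo + (3 - 1.5) - 1e-9))
  expect_true(all(sweep(xyz, 2, box_hi) <= -(3 - 1.5) + 1e-9))
  expect_error(make_grid(list(m), spacing = 0), "spacing")
  expect_error(make_grid(list(m), margin = -1), "margin")
  expect_error(make_grid(list()), "empty")
})

test_that("CoMFA probe energies match closed forms and truncation rules", {
  # single +1 e atom, probe +1 e, eps(r) = r: 332.0637 / r^2
  m <- molecule("q", "C", rbind(c(0, 0, 0)), charge = 1)
  g <- structure(list(origin = c(4, 0, 0), spacing = 1, dims = c(1L, 1L, 1L)),
                 class = "qsar_grid")
  f <- comfa_fields(m, g)
  expect_equal(f$electrostatic, 332.0637 / 16, tolerance = 1e-6)
  expect_equal(f$electrostatic, 20.754, tolerance = 1e-4)
  # steric at the LJ minimum distance equals -sqrt(eps_probe * eps_C)
  gmin <- structure(list(origin = c(3.4, 0, 0), spacing = 1,
                         dims = c(1L, 1L, 1L)), class = "qsar_grid")
  expect_equal(comfa_fields(m, gmin)$steric, -0.107, tolerance = 1e-9)
  # node on the atom center: steric clamps at +30 and flags a clash
  gon <- structure(list(origin = c(0, 0, 0), spacing = 1,
                        dims = c(1L, 1L, 1L)), class = "qsar_grid")
  fon <- comfa_fields(m, gon)
  expect_equal(fon$steric, 30)
  expect_true(fon$clash)
  # far node of an uncharged molecule: both fields vanish
  neutral <- molecule("n", c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  gfar <- structure(list(origin = c(20, 0, 0), spacing = 1,
                         dims = c(1L, 1L, 1L)), class = "qsar_grid")
  ffar <- comfa_fields(neutral, gfar)
  expect_lt(abs(ffar$steric), 1e-3)
  expect_identical(ffar$electrostatic, 0)
})

test_that("CoMFA energies respect the truncation bounds everywhere", {
  synth <- default_synth()
  g <- synth$truth$grid
  for (m in synth$molecules[c(1, 20, 40)]) {
    f <- comfa_fields(m, g)
    expect_true(all(f$steric <= 30))
    expect_true(all(abs(f$electrostatic) <= 30))
  }
})

test_that("CoMSIA similarity matches hand-evaluated Gaussians", {
  m <- molecule("w", "C", rbind(c(0, 0, 0)), hydrophobic_w = 1)
  node_at <- function(x) {
    structure(list(origin = c(x, 0, 0), spacing = 1, dims = c(1L, 1L, 1L)),
              class = "qsar_grid")
  }
  f0 <- comsia_fields(m, node_at(0), kinds = "hydrophobic")
  expect_equal(f0$hydrophobic, -1)
  f1 <- comsia_fields(m, node_at(1), kinds = "hydrophobic")
  expect_equal(f1$hydrophobic, -exp(-0.3), tolerance = 1e-9)
  expect_equal(f1$hydrophobic, -0.74082, tolerance = 1e-5)
  # steric atom weight follows the r_vdw^3 convention
  fs <- comsia_fields(m, node_at(1), kinds = "steric")
  expect_equal(fs$steric, -1.70^3 * exp(-0.3), tolerance = 1e-9)
  # additivity over atoms
  two <- molecule("w2", c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)),
                  hydrophobic_w = c(1, 0.5))
  f2 <- comsia_fields(two, node_at(1), kinds = "hydrophobic")
  expect_equal(f2$hydrophobic,
               -(exp(-0.3) + 0.5 * exp(-0.3)), tolerance = 1e-12)
})

test_that("CoMSIA attenuation limit alpha -> 0 gives total weights", {
  set.seed(3)
  m <- molecule("r", rep("C", 5), matrix(rnorm(15, sd = 2), 5),
                hydrophobic_w = runif(5), donor_w = rbinom(5, 1, 0.5))
  g <- make_grid(list(m), spacing = 3, margin = 3)
  probe0 <- default_probe(attenuation_alpha = 1e-9)
  f <- comsia_fields(m, g, probe0, kinds = c("hydrophobic", "donor"))
  expect_equal(unique(round(f$hydrophobic, 6)),
               round(-sum(m$atoms$hydrophobic_w), 6))
  expect_equal(unique(round(f$donor, 6)), round(-sum(m$atoms$donor_w), 6))
})

test_that("fields are translation-equivariant and deterministic", {
  m <- toy_mol()
  m <- assign_property_weights(m)
  m$atoms$charge <- c(0.2, -0.1, -0.3, 0.2)
  g <- make_grid(list(m), spacing = 2, margin = 4)
  shift <- c(5.5, -2.25, 1.75)
  m2 <- m
  coords(m2) <- sweep(coords(m), 2, -shift)
  g2 <- g
  g2$origin <- g$origin + shift
  f1 <- comfa_fields(m, g)
  f2 <- comfa_fields(m2, g2)
  expect_lt(max(abs(f1$steric - f2$steric)), 1e-9)
  expect_lt(max(abs(f1$electrostatic - f2$electrostatic)), 1e-9)
  s1 <- comsia_fields(m, g)
  s2 <- comsia_fields(m2, g2)
  for (k in names(s1)) expect_lt(max(abs(s1[[k]] - s2[[k]])), 1e-9)
  # recomputation is bit-identical
  expect_identical(comfa_fields(m, g), comfa_fields(m, g))
  expect_identical(comsia_fields(m, g), comsia_fields(m, g))
})

test_that("block assembly filters constant columns and scales fields", {
  # constructed fixture: 2 varying + 3 constant columns in one kind
  fs <- structure(list(
    fields = list(alpha = cbind(c(1, 5, 9), c(0, 0, 0), c(2, 2, 2)),
                  beta = cbind(c(0, 4, 8), c(7, 7, 7))),
    clash = NULL,
    grid = structure(list(origin = c(0, 0, 0), spacing = 1,
                          dims = c(3L, 1L, 1L)), class = "qsar_grid"),
    model = "comsia", ids = c("a", "b", "c")), class = "qsar_fieldset")
  # dims differ across kinds -> error
  expect_error(build_block(fs), "inconsistent")
  fs$fields$beta <- cbind(fs$fields$beta, c(7, 7, 7))
  blk <- build_block(fs, filter_sigma = 0.5, scaling = "comfa_std")
  expect_equal(sum(blk$kept_mask), 2L)
  expect_equal(blk$column_meta$kind, c("alpha", "beta"))
  # post-scaling per-field total variances are equal
  v <- tapply(apply(blk$matrix, 2, sd)^2, blk$column_meta$kind, sum)
  expect_equal(unname(v[1]), unname(v[2]), tolerance = 1e-9)
  # all-constant input errors
  fs0 <- fs
  fs0$fields <- lapply(fs$fields, function(m) m * 0)
  expect_error(build_block(fs0, filter_sigma = 0.5), "all columns")
})

test_that("clashed electrostatic values are replaced by the column mean", {
  fs <- structure(list(
    fields = list(steric = cbind(c(30, 1, 2)),
                  electrostatic = cbind(c(25, -4, -6))),
    clash = cbind(c(TRUE, FALSE, FALSE)),
    grid = structure(list(origin = c(0, 0, 0), spacing = 1,
                          dims = c(1L, 1L, 1L)), class = "qsar_grid"),
    model = "comfa", ids = c("a", "b", "c")), class = "qsar_fieldset")
  blk <- build_block(fs, filter_sigma = 0.1, scaling = "none")
  e <- blk$matrix[, blk$column_meta$kind == "electrostatic"]
  expect_equal(e[1], mean(c(-4, -6)))  # clashed entry -> mean of the rest
  expect_equal(e[2:3], c(-4, -6))
})
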