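test_that("IC50 to pIC50 conversion matches the printed activity table", {
  tab <- read.csv(activities_path())
  # printed pIC50 column reproduced within 1e-4 for all 40 rows
  expect_lt(max(abs(ic50_to_pic50(tab$ic50_uM) - tab$pic50)), 1e-4)
  # spot values at full precision against the 5-decimal printed column
  expect_equal(ic50_to_pic50(0.54), 6.26761, tolerance = 1e-4)
  expect_equal(ic50_to_pic50(0.00825), 8.08355, tolerance = 1e-4)
  expect_equal(ic50_to_pic50(25.64), 4.59108, tolerance = 1e-4)
  expect_identical(ic50_to_pic50(1.0), 6)
})

test_that("pIC50 conversion round-trips and rejects bad input", {
  x <- c(0.00825, 0.54, 25.64, 1e-3, 500)
  expect_equal(pic50_to_ic50(ic50_to_pic50(x)), x, tolerance = 1e-9)
  expect_error(ic50_to_pic50(0), "finite and > 0")
  expect_error(ic50_to_pic50(-1), "finite and > 0")
  expect_error(ic50_to_pic50(NaN), "finite and > 0")
})

test_that("activity reader fills pIC50, checks consistency, flags roles", {
  tab <- read_activities(activities_path())
  expect_equal(nrow(tab), 40L)
  expect_equal(sum(tab$role == "test"), 10L)
  expect_setequal(tab$id[tab$role == "test"],
                  as.character(c(2, 8, 11, 14, 17, 23, 24, 29, 33, 39)))

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,ic50_uM", "a,1.0", "b,0.1"), tmp)
  filled <- read_activities(tmp)
  expect_equal(filled$pic50, c(6, 7))
  expect_true(all(filled$role == "training"))

  writeLines(c("id,ic50_uM,pic50", "a,1.0,9.9"), tmp)
  expect_error(read_activities(tmp), "inconsistent")
  writeLines(c("id,ic50_uM", "a,1.0", "a,0.2"), tmp)
  expect_error(read_activities(tmp), "duplicate")
})

test_that("dataset reader matches structures to activities strictly", {
  mols <- lapply(1:3, function(i) toy_mol(sprintf("cpd%d", i)))
  sdf <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, sdf)
  act <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,ic50_uM,role", "cpd1,0.5,training", "cpd2,1,training",
               "cpd3,2,test"), act)
  ds <- read_dataset(sdf, act)
  expect_length(ds$molecules, 3L)
  expect_equal(ds$records$id, c("cpd1", "cpd2", "cpd3"))
  expect_equal(ds$records$pic50[1], 6 - log10(0.5))
  # round trip preserved coordinates
  expect_equal(coords(ds$molecules[[2]]), coords(mols[[2]]),
               ignore_attr = TRUE, tolerance = 1e-4)

  writeLines(c("id,ic50_uM", "cpd1,0.5", "cpd2,1", "cpd3,2", "ghost,1"), act)
  expect_error(read_dataset(sdf, act), "ghost")
  empty <- withr::local_tempfile(fileext = ".sdf")
  writeLines("", empty)
  expect_error(read_dataset(empty, act))
})

test_that("MOL2 reader recovers coordinates, charges and bonds", {
  mol2 <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c(
    "@<TRIPOS>MOLECULE", "ethanolish", " 3 2 0 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 C1  0.000  0.000  0.000 C.3  1 LIG  0.1500",
    "  2 O1  1.400  0.000  0.000 O.3  1 LIG -0.4500",
    "  3 H1  1.800  0.900  0.000 H    1 LIG  0.3000",
    "@<TRIPOS>BOND", "  1 1 2 1", "  2 2 3 1"
  ), mol2)
  mols <- read_mol2(mol2)
  expect_length(mols, 1L)
  m <- mols[[1]]
  expect_equal(m$atoms$element, c("C", "O", "H"))
  expect_equal(m$atoms$charge, c(0.15, -0.45, 0.30))
  expect_equal(nrow(m$bonds), 2L)
  expect_equal(coords(m)[2, ], c(x = 1.4, y = 0, z = 0))
})

test_that("PEOE charges conserve charge and polarize C-H correctly", {
  ch <- molecule("ch", c("C", "H"), rbind(c(0, 0, 0), c(1.09, 0, 0)),
                 bonds = rbind(c(1, 2)))
  got <- assign_peoe_charges(ch)
  expect_lt(got$atoms$charge[1], 0)
  expect_gt(got$atoms$charge[2], 0)
  expect_lt(abs(sum(got$atoms$charge)), 1e-6)
  # independent hand-iterated oracle, several molecules
  meoh <- molecule("meoh", c("C", "O", "H", "H", "H", "H"),
                   rbind(c(0, 0, 0), c(1.4, 0, 0), c(2, 0.8, 0),
                         c(-0.5, 0.9, 0), c(-0.5, -0.9, 0.3),
                         c(-0.3, 0, -1)),
                   bonds = rbind(c(1, 2), c(2, 3), c(1, 4), c(1, 5), c(1, 6)))
  for (mol in list(ch, meoh)) {
    got <- assign_peoe_charges(mol, n_iter = 6)
    want <- peoe_oracle(mol$atoms$element, mol$bonds, 6)
    expect_equal(got$atoms$charge, want, tolerance = 1e-12)
  }
  # damping: two-atom toy increments between sweeps 5 and 6 below 1e-3 e,
  # and increments decay monotonically for the larger molecule
  q5 <- assign_peoe_charges(ch, n_iter = 5)$atoms$charge
  q6 <- assign_peoe_charges(ch, n_iter = 6)$atoms$charge
  expect_lt(max(abs(q6 - q5)), 1e-3)
  inc <- vapply(4:7, function(k) {
    assign_peoe_charges(meoh, n_iter = k)$atoms$charge
  }, numeric(6))
  steps <- apply(abs(inc[, -1] - inc[, -4]), 2, max)
  expect_true(all(diff(steps) < 0))
  expect_error(assign_peoe_charges(
    molecule("x", c("Xx", "H"), rbind(c(0, 0, 0), c(1, 0, 0)),
             bonds = rbind(c(1, 2)))), "Xx")
})

test_that("PEOE charge assignment is permutation-invariant", {
  m <- toy_mol("perm")
  perm <- c(3, 1, 4, 2)
  inv <- order(perm)
  m2 <- molecule("perm2", m$atoms$element[perm], coords(m)[perm, ],
                 bonds = matrix(inv[m$bonds], ncol = 2), skeleton = 1:4)
  q1 <- assign_peoe_charges(m)$atoms$charge
  q2 <- assign_peoe_charges(m2)$atoms$charge
  expect_equal(q2, q1[perm], tolerance = 1e-12)
})

test_that("property weight rules flag donors, acceptors, lipophilic atoms", {
  # carbonyl-like: C=O plus an amide N-H
  m <- molecule("amide", c("C", "O", "N", "H", "C"),
                rbind(c(0, 0, 0), c(1.2, 0, 0), c(-0.7, 1.1, 0),
                      c(-0.3, 2.0, 0), c(-2.1, 1.2, 0)),
                bonds = rbind(c(1, 2), c(1, 3), c(3, 4), c(3, 5)))
  got <- assign_property_weights(m)
  expect_equal(got$atoms$acceptor_w[2], 1)  # carbonyl O accepts
  expect_equal(got$atoms$donor_w[2], 0)     # ...but has no H
  expect_equal(got$atoms$donor_w[3], 1)     # N-H donates
  expect_equal(got$atoms$donor_w[5], 0)
  expect_gt(got$atoms$hydrophobic_w[5], 0)  # carbon lipophilic
  expect_lt(got$atoms$hydrophobic_w[2], 0)  # oxygen hydrophilic
  bad <- molecule("bad", c("C", "Zz"), rbind(c(0, 0, 0), c(1, 0, 0)),
                  bonds = rbind(c(1, 2)))
  expect_error(assign_property_weights(bad), "Zz")
})

test_that("train/test split nests the test activity range and sizes 75/25", {
  rec <- read_activities(activities_path())
  # the fixture's explicit test set satisfies the range condition
  explicit <- rec$id[rec$role == "test"]
  sp <- split_train_test(rec, explicit_test_ids = explicit, seed = 123)
  expect_setequal(sp$test_ids, explicit)
  expect_length(sp$training_ids, 30L)
  ytest <- rec$pic50[rec$id %in% sp$test_ids]
  ytrain <- rec$pic50[rec$id %in% sp$training_ids]
  expect_lte(max(ytest), max(ytrain))
  expect_gte(min(ytest), min(ytrain))
  # explicit split ignores the seed entirely
  sp2 <- split_train_test(rec, explicit_test_ids = explicit, seed = 999)
  expect_identical(sp, sp2)

  # random draws: size, nesting, determinism
  for (s in c(1, 5, 11)) {
    r <- split_train_test(rec, training_fraction = 0.75, seed = s)
    expect_length(r$training_ids, 30L)
    expect_length(r$test_ids, 10L)
    yt <- rec$pic50[rec$id %in% r$test_ids]
    yr <- rec$pic50[rec$id %in% r$training_ids]
    expect_lte(max(yt), max(yr))
    expect_gte(min(yt), min(yr))
    expect_identical(r, split_train_test(rec, training_fraction = 0.75,
                                         seed = s))
  }
  # an explicit test set holding the global maximum must be rejected
  expect_error(split_train_test(rec, explicit_test_ids = c("1", "2", "3")),
               "range condition")
})
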