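test_that("C-alpha parsing handles minimal PDB files", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.500  -1.250   0.125  1.00  0.00           C",
    "ATOM      4  CA  SER A   3      -2.000   0.500   9.875  1.00  0.00           C",
    "TER", "END"), path)
  cs <- read_calpha(path)
  expect_equal(nrow(cs), 3L)
  expect_equal(cs$resno, 1:3)
  expect_equal(cs$x, c(1.0, 4.5, -2.0))
  expect_equal(cs$z[3], 9.875)

  het <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  CU  CU  A 301       0.000   0.000   0.000  1.00  0.00          CU",
    "END"), het)
  expect_error(read_calpha(het), class = "lpmominer_empty_model")
})

test_that("PDB writing round-trips at format precision", {
  set.seed(91)
  cs <- make_coil_coords(25, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_calpha_pdb(cs, path)
  back <- read_calpha(path)
  expect_equal(back$resno, cs$resno)
  expect_equal(back$x, cs$x, tolerance = 1e-3)
  expect_equal(back$y, cs$y, tolerance = 1e-3)
  expect_equal(back$z, cs$z, tolerance = 1e-3)
})

test_that("Kabsch superposition is exact on rigid copies", {
  ref <- make_fold_coords(60)
  sp0 <- kabsch_superpose(ref, ref)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)

  p <- perturb_structure(ref, sigma = 0, seed = 5)
  sp <- kabsch_superpose(ref, p$coords)
  expect_lt(sp$rmsd, 1e-6)
  # recovered rotation inverts the applied one
  expect_equal(sp$rotation %*% p$truth$rotation, diag(3), tolerance = 1e-6)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  # the stated transformation actually reproduces the stated rmsd
  moved <- apply_superposition(sp, p$coords)
  expect_equal(sqrt(mean(rowSums((coord_xyz(moved) - coord_xyz(ref))^2))),
               sp$rmsd, tolerance = 1e-9)

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]),
               class = "lpmominer_validation")
  expect_error(kabsch_superpose(ref, ref[1:10, ]),
               class = "lpmominer_validation")
})

test_that("Kabsch rmsd matches the independent least-squares fit on noisy sets", {
  ref <- make_fold_coords(50)
  for (k in 1:5) {
    p <- perturb_structure(ref, sigma = 0.5, seed = 10 + k)
    got <- kabsch_superpose(ref, p$coords)$rmsd
    fx <- as.vector(t(coord_xyz(ref)))
    mx <- as.vector(t(coord_xyz(p$coords)))
    fitted <- suppressWarnings(bio3d::fit.xyz(fixed = fx, mobile = mx))
    dev <- matrix(fitted - fx, ncol = 3, byrow = TRUE)
    want <- sqrt(mean(rowSums(dev^2)))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("rmsd is symmetric, rigid-invariant and never beaten by no fit", {
  ref <- make_fold_coords(40)
  p <- perturb_structure(ref, sigma = 1.0, seed = 33)$coords
  expect_equal(kabsch_superpose(ref, p)$rmsd, kabsch_superpose(p, ref)$rmsd,
               tolerance = 1e-9)
  # common rigid transformation of both sets leaves rmsd unchanged
  q1 <- perturb_structure(ref, sigma = 0, seed = 44)$coords
  q2 <- perturb_structure(p, sigma = 0, seed = 44)$coords
  expect_equal(kabsch_superpose(q1, q2)$rmsd, kabsch_superpose(ref, p)$rmsd,
               tolerance = 1e-6)
  raw <- sqrt(mean(rowSums((coord_xyz(ref) - coord_xyz(p))^2)))
  expect_lte(kabsch_superpose(ref, p)$rmsd, raw + 1e-9)
})

test_that("sliding windows find planted domains", {
  ref <- make_fold_coords(40)
  model <- make_structure_model(ref, plant = TRUE, n_before = 30,
                                n_after = 25, sigma = 0, seed = 3)
  best <- sliding_domain_match(model$coords, ref)
  expect_equal(best$span, model$truth$span)
  expect_lt(best$superposition$rmsd, 1e-6)

  # coarser stride can never do better than stride one
  best5 <- sliding_domain_match(model$coords, ref, step = 5)
  expect_gte(best5$superposition$rmsd, best$superposition$rmsd - 1e-12)

  # of two embedded copies, the cleaner one wins
  noisy <- perturb_structure(ref, sigma = 1.5, seed = 9)$coords
  clean <- perturb_structure(ref, sigma = 0, seed = 10)$coords
  stack <- rbind(coord_xyz(noisy), coord_xyz(make_coil_coords(15, 2)),
                 coord_xyz(clean))
  model2 <- coord_set(seq_len(nrow(stack)), stack[, 1], stack[, 2], stack[, 3])
  best2 <- sliding_domain_match(model2, ref)
  expect_equal(best2$start_index, 40 + 15 + 1)

  expect_error(sliding_domain_match(ref[1:10, ], ref),
               class = "lpmominer_validation")
})

test_that("GbpA_3-like classification separates planted folds from coils", {
  ref <- make_fold_coords(40)
  model <- make_structure_model(ref, plant = TRUE, sigma = 0, seed = 12)
  got <- classify_gbpa3_like(model$coords, model$truth$span, ref)
  expect_true(got$gbpa3_like)
  expect_lt(got$rmsd, 1e-6)
  # a zero cutoff still admits exact copies
  expect_true(classify_gbpa3_like(model$coords, model$truth$span, ref,
                                  rmsd_cutoff = 1e-6)$gbpa3_like)

  for (k in 1:10) {
    coil <- make_structure_model(ref, plant = FALSE, seed = 100 + k)
    got2 <- classify_gbpa3_like(coil$coords, c(41, 90), ref)
    expect_false(got2$gbpa3_like)
  }

  # too-short segments cannot reach the coverage requirement
  short <- classify_gbpa3_like(model$coords, c(51, 60), ref)
  expect_false(short$gbpa3_like)
})
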