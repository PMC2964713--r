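write_mini_pdb <- function(path) {
  lines <- c(
    "HEADER    TEST STRUCTURE",
    "ATOM      1  N   MET A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  MET A   1       1.400   0.000   0.000  1.00  0.00           C",
    "ATOM      3  H   MET A   1       1.400   1.000   0.000  1.00  0.00           H",
    "ATOM      4  CA AALA A   2       3.000   4.000   0.000  0.50  0.00           C",
    "ATOM      5  CA BALA A   2       3.100   4.100   0.000  0.50  0.00           C",
    "ATOM      6  CB  ALA A   2       3.000   4.000   2.000  1.00  0.00           C",
    "ATOM      7  CA  LYS A   3       8.000   0.000   0.000  1.00  0.00           C",
    "HETATM    8  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    "TER",
    "END")
  writeLines(lines, path)
  path
}

test_that("PDB parsing keeps heavy atoms, first altloc, and drops waters", {
  path <- write_mini_pdb(withr::local_tempfile(fileext = ".pdb"))
  model <- parse_structure(path)
  expect_equal(nrow(model$residues), 3)
  expect_false(any(model$atoms$element == "H"))
  expect_false(any(model$atoms$resid %in% c("HOH", "WAT")))
  # first altloc instance kept: exactly one CA in residue 2
  a2 <- model$atoms[model$atoms$res_key == "A:2", ]
  expect_equal(sum(a2$elety == "CA"), 1)
  expect_equal(a2$x[a2$elety == "CA"], 3.0)
  expect_equal(model$residues$aa, c("M", "A", "K"))
})

test_that("inter-residue distances match hand values and brute force", {
  # 3-4-5 triangle with single atoms
  expect_identical(mean_residue_distance(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))), 5)
  # mean of 4 and 2
  A <- rbind(c(0, 0, 0), c(0, 0, 2)); B <- rbind(c(0, 0, 4))
  expect_equal(mean_residue_distance(A, B), 3)
  expect_equal(min_atom_distance(A, B), 2)
  expect_true(contact(A, B))
  # exact boundary is inclusive
  expect_true(contact(rbind(c(0, 0, 0)), rbind(c(4, 0, 0)), cutoff = 4))
  expect_false(contact(rbind(c(0, 0, 0)), rbind(c(4.0001, 0, 0)), cutoff = 4))

  set.seed(17)
  for (rep in 1:40) {
    A <- matrix(rnorm(3 * sample(1:5, 1), sd = 4), ncol = 3)
    B <- matrix(rnorm(3 * sample(1:5, 1), sd = 4), ncol = 3)
    expect_equal(mean_residue_distance(A, B), oracle_mean_dist(A, B),
                 tolerance = 1e-10)
    expect_equal(min_atom_distance(A, B), oracle_min_dist(A, B),
                 tolerance = 1e-10)
    expect_lte(min_atom_distance(A, B), mean_residue_distance(A, B) + 1e-12)
  }
})

test_that("contact maps are symmetric and consistent with pair operators", {
  st <- simulate_structure(10, planted_contacts = rbind(c(2, 7)), seed = 3)
  cm <- contact_map(st$model)
  expect_true(all(cm$pairs$min_dist <= cm$pairs$mean_dist + 1e-12))
  expect_identical(cm$pairs$contact, cm$pairs$min_dist <= cm$cutoff)
  k <- st$model$residues$res_key
  expect_lte(compevo:::cm_min_dist(cm, k[2], k[7]), 4)
  expect_identical(compevo:::cm_min_dist(cm, k[2], k[7]),
                   compevo:::cm_min_dist(cm, k[7], k[2]))
  expect_equal(compevo:::cm_min_dist(cm, k[1], k[4]),
               min_atom_distance(residue_atoms(st$model, 1),
                                 residue_atoms(st$model, 4)),
               tolerance = 1e-10)
})

test_that("mass-centre RMSD is zero on self and invariant to rigid motion", {
  st <- simulate_structure(12, seed = 8)
  expect_equal(mass_center_rmsd(st$model, st$model), 0, tolerance = 1e-12)
  set.seed(4)
  for (rep in 1:10) {
    # random rotation + translation of the same structure
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    shift <- rnorm(3, sd = 10)
    rot <- st$model
    xyz <- as.matrix(rot$atoms[, c("x", "y", "z")]) %*% q
    rot$atoms$x <- xyz[, 1] + shift[1]
    rot$atoms$y <- xyz[, 2] + shift[2]
    rot$atoms$z <- xyz[, 3] + shift[3]
    expect_lt(mass_center_rmsd(st$model, rot, superpose = TRUE), 1e-8)
    expect_equal(mass_center_rmsd(st$model, rot),
                 mass_center_rmsd(rot, st$model), tolerance = 1e-9)
  }
})

test_that("disabling superposition measures the raw frame offset", {
  # two 3-point toys whose centres differ by exactly 1 A in x
  mk <- function(dx) {
    atoms <- tibble::tibble(
      chain = "A", resno = 1:3, icode = "", resid = "GLY", elety = "CA",
      element = "C", mass = 12.011,
      x = c(0, 3, 6) + dx, y = c(0, 4, 0), z = 0,
      res_key = paste0("A:", 1:3))
    residues <- tibble::tibble(res_key = atoms$res_key, chain = "A",
                               resno = 1:3, icode = "", resid = "GLY",
                               aa = "G", n_atoms = 1L)
    structure(list(atoms = atoms, residues = residues, source = "toy"),
              class = "structure_model")
  }
  expect_equal(mass_center_rmsd(mk(0), mk(1), superpose = FALSE), 1)
  expect_error(mass_center_rmsd(mk(0), mk(1), pairing = cbind(1:2, 1:2),
                                superpose = TRUE),
               class = "compevo_degenerate_error")
})

test_that("alignment-structure mapping handles gaps and missing residues", {
  st <- simulate_structure(3, seed = 5, residue_names = c("M", "K", "L"))
  aln <- protein_alignment(c(ref = "MK-L", o1 = "MKAL", o2 = "MRAL",
                             o3 = "MKAI"))
  map <- map_alignment_to_structure(aln, "ref", st$model)
  got <- map$map[!is.na(map$map$ref_resno), ]
  expect_equal(got$column, c(1L, 2L, 4L))
  expect_equal(got$ref_resno, 1:3)
  expect_true(is.na(map$map$ref_resno[map$map$column == 3]))
  expect_identical(compevo:::site_label(map, 2), "K2")

  # structure missing a residue (gap in density): column flagged unmapped
  st4 <- simulate_structure(3, seed = 6, residue_names = c("M", "K", "I"))
  aln4 <- protein_alignment(c(ref = "MKLI", o1 = "MKLI", o2 = "MRLI",
                              o3 = "MKLV"))
  map4 <- map_alignment_to_structure(aln4, "ref", st4$model)
  expect_true(is.na(map4$map$ref_resno[map4$map$column == 3]))
  expect_equal(map4$map$ref_resno[map4$map$column == 4], 3)

  expect_error(map_alignment_to_structure(aln, "nope", st$model),
               class = "compevo_id_error")
})
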