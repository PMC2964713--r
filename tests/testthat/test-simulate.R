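test_that("coupling at rho = 1 forces the partner onto the driver's branches", {
  cfg <- sim_config(seed = 9, n_taxa = 10, n_codons = 30,
                    planted_pairs = data.frame(site_a = 5, site_b = 20,
                                               rho = 1))
  sim <- simulate_alignment(cfg)
  cnt <- sim$ground_truth$counts
  drv <- cnt$nonsyn[cnt$codon == 5] > 0
  par <- cnt$nonsyn[cnt$codon == 20] > 0
  expect_identical(drv, par)
})

test_that("omega = 0 leaves the protein alignment invariant", {
  sim <- simulate_alignment(sim_config(seed = 4, n_taxa = 8, n_codons = 25,
                                       omega = 0))
  expect_true(all(apply(sim$protein_aln$mat, 2,
                        function(cc) length(unique(cc))) == 1))
  # synonymous variation still happens
  expect_gt(sum(sim$ground_truth$counts$syn), 0)
})

test_that("invariant columns never change and the config validates", {
  sim <- simulate_alignment(sim_config(seed = 6, n_taxa = 8, n_codons = 20,
                                       invariant_sites = c(3, 11)))
  cnt <- sim$ground_truth$counts
  expect_equal(sum(cnt$syn[cnt$codon %in% c(3, 11)]), 0)
  expect_equal(sum(cnt$nonsyn[cnt$codon %in% c(3, 11)]), 0)
  expect_error(sim_config(planted_pairs = data.frame(site_a = 1, site_b = 1,
                                                     rho = 0.5)),
               "distinct")
  expect_error(sim_config(planted_windows = data.frame(branch = "x", start = 50,
                                                       end = 70, omega = 2)),
               "range")
  expect_error(sim_config(planted_pairs = data.frame(site_a = 1, site_b = 2,
                                                     rho = 1.4)))
})

test_that("simulation is reproducible and scales with tree length", {
  s1 <- simulate_alignment(sim_config(seed = 12, n_taxa = 8, n_codons = 30))
  s2 <- simulate_alignment(sim_config(seed = 12, n_taxa = 8, n_codons = 30))
  expect_identical(s1$codon_aln$codons, s2$codon_aln$codons)

  tree <- s1$tree
  tot <- function(scale, seeds) {
    t2 <- tree; t2$edge.length <- tree$edge.length * scale
    mean(vapply(seeds, function(sd) {
      sim <- simulate_alignment(sim_config(seed = sd, n_taxa = 8,
                                           n_codons = 30, tree = t2))
      sum(sim$ground_truth$counts$syn + sim$ground_truth$counts$nonsyn)
    }, numeric(1)))
  }
  base <- tot(1, 1:25)
  doubled <- tot(2, 101:125)
  expect_gt(doubled / base, 1.6)
  expect_lt(doubled / base, 2.4)
})

test_that("toy structures realise planted geometry deterministically", {
  st <- simulate_structure(15, planted_contacts = rbind(c(3, 11)),
                           planted_mediators = rbind(c(4, 13, 8)), seed = 21)
  m <- st$model
  expect_lte(min_atom_distance(residue_atoms(m, 3), residue_atoms(m, 11)), 4)
  expect_gt(min_atom_distance(residue_atoms(m, 4), residue_atoms(m, 13)), 4)
  expect_lte(min_atom_distance(residue_atoms(m, 8), residue_atoms(m, 4)), 4)
  expect_lte(min_atom_distance(residue_atoms(m, 8), residue_atoms(m, 13)), 4)

  # byte-identical regeneration from the same seed
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  simulate_structure(15, planted_contacts = rbind(c(3, 11)), seed = 21,
                     path = p1)
  simulate_structure(15, planted_contacts = rbind(c(3, 11)), seed = 21,
                     path = p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("an unconstrained chain keeps consecutive spacing near 3.8 A", {
  st <- simulate_structure(20, seed = 2)
  cen <- compevo:::residue_centres(st$model, weighted = FALSE)
  steps <- sqrt(rowSums(diff(cen)^2))
  expect_true(all(abs(steps - 3.8) < 0.8))
})

test_that("the bundled fixture regenerates identically and parses cleanly", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- make_fixture(d1)
  f2 <- make_fixture(d2)
  for (nm in c("protein_fasta", "cds_fasta", "tree", "pdb", "regions",
               "ground_truth"))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]))
  # every emitted file is a valid input to its module
  prot <- read_alignment(f1$protein_fasta, "protein")
  cds <- read_alignment(f1$cds_fasta, "nucleotide")
  caln <- backtranslate(prot, cds)
  expect_equal(ncol(caln$codons), 60)
  tr <- ape::read.tree(f1$tree)
  expect_setequal(tr$tip.label, prot$taxa)
  model <- parse_structure(f1$pdb)
  expect_equal(nrow(model$residues), 60)
  regions <- read_regions(f1$regions)
  expect_true("active_site" %in% names(regions))
})
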