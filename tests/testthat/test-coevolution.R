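# small helper: alignment + identity-ish divergence matrix for the
# pair-space correlation operation
toy_pair_divergence <- function(taxa, value = 0.3) {
  n <- length(taxa)
  t_kl <- matrix(value, n, n, dimnames = list(taxa, taxa))
  t_kl <- t_kl + outer(seq_len(n), seq_len(n), function(i, j) abs(i - j)) / 50
  diag(t_kl) <- 0
  t_kl
}

test_that("pair-space correlation obeys the self, zero-variance and identity rules", {
  aln <- protein_alignment(c(a = "MKAK", b = "MRAR", c = "MKAK", d = "MRAR",
                             e = "MKAK", f = "MRAR"))
  t_kl <- toy_pair_divergence(aln$taxa)
  # a variable site with itself
  expect_equal(caps_correlation(aln, t_kl, 2, 2), 1)
  # invariant partner column -> 0 by the zero-variance rule
  expect_equal(caps_correlation(aln, t_kl, 2, 3), 0)
  # identical columns -> identical residual vectors -> 1
  expect_equal(caps_correlation(aln, t_kl, 2, 4), 1)
  # symmetry
  expect_equal(caps_correlation(aln, t_kl, 2, 4),
               caps_correlation(aln, t_kl, 4, 2))
})

test_that("pair-space correlation is invariant under uniform time rescaling", {
  set.seed(19)
  sim <- simulate_alignment(sim_config(seed = 3, n_taxa = 8, n_codons = 30))
  aln <- sim$protein_aln
  t_kl <- pairwise_synonymous_distance(sim$codon_aln)$t
  v <- which(apply(aln$mat, 2, function(cc) length(unique(cc))) >= 2)[1:2]
  r1 <- caps_correlation(aln, t_kl, v[1], v[2])
  r2 <- caps_correlation(aln, 3.7 * t_kl, v[1], v[2])
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("branch rate profiles count changes and respect the change filter", {
  sim <- simulate_alignment(sim_config(seed = 21, n_taxa = 10, n_codons = 50))
  rates <- coevolution_rates(sim$codon_aln, sim$tree)
  expect_equal(nrow(rates$R), nrow(sim$tree$edge))
  expect_true(all(rates$n_changes >= 0))
  expect_true(all(rates$t_branch > 0))
  # column centring
  expect_true(all(abs(colMeans(rates$R)) < 1e-10))
})

test_that("the permutation null is seeded and refuses tiny draws", {
  sim <- simulate_alignment(sim_config(seed = 21, n_taxa = 10, n_codons = 50))
  rates <- coevolution_rates(sim$codon_aln, sim$tree)
  n1 <- permutation_null(rates, n_perm = 2000, seed = 5)
  n2 <- permutation_null(rates, n_perm = 2000, seed = 5)
  expect_identical(n1$null_stat, n2$null_stat)
  expect_error(permutation_null(rates, n_perm = 50, seed = 5), "uninformative")
})

test_that("null quantiles match exhaustive branch permutation on a tiny instance", {
  # two sites, five branches with changes: enumerate all 120 permutations
  R <- cbind(a = c(1, 1, 0, 0, 0), b = c(1, 0, 1, 0, 0))
  R <- sweep(R, 2, colMeans(R))
  exact <- apply(gtools_perms(5), 1, function(p)
    sum(R[p, 1] * R[, 2]) / 4)
  rates <- structure(list(R = R, branches = paste0("b", 1:5),
                          t_branch = rep(1, 5), n_changes = c(a = 2, b = 2),
                          taxa = letters[1:4]),
                     class = "coevolution_rates")
  null <- permutation_null(rates, n_perm = 4000, seed = 2, min_changes = 2)
  # the null distribution is discrete: compare atom probabilities
  for (thr in c(0.29, 0.1, 0.04))
    expect_equal(mean(abs(null$null_stat) >= thr), mean(abs(exact) >= thr),
                 tolerance = 0.25)
})

test_that("step-down adjustment is monotone and handles edge cases", {
  sim <- simulate_alignment(sim_config(
    seed = 8, n_taxa = 12, n_codons = 60,
    planted_pairs = data.frame(site_a = 10, site_b = 40, rho = 1)))
  rates <- coevolution_rates(sim$codon_aln, sim$tree)
  obs <- compevo:::observed_correlations(rates, 3)
  null <- permutation_null(rates, n_perm = 5000, seed = 4)
  adj <- stepdown_adjust(obs, null)
  expect_true(all(adj$p_adj >= adj$p_raw - 1e-12))
  ord <- order(-abs(adj$stat), adj$site_a, adj$site_b)
  expect_true(all(diff(adj$p_adj[ord]) >= -1e-12))
  # the perfectly coupled planted pair attains the minimum adjusted p
  key <- paste(adj$site_a, adj$site_b)
  if ("10 40" %in% key)
    expect_lte(adj$p_adj[key == "10 40"], min(adj$p_adj) + 1e-12)
})

test_that("detect_coevolution returns a sorted, annotated pair table", {
  sim <- simulate_alignment(sim_config(
    seed = 47, n_taxa = 12, n_codons = 60,
    planted_pairs = data.frame(site_a = c(12, 20), site_b = c(27, 44),
                               rho = 0.9)))
  res <- detect_coevolution(sim$protein_aln, sim$codon_aln, sim$tree,
                            n_perm = 5000, seed = 3)
  expect_s3_class(res, "coevolution_result")
  expect_true(all(c("rho", "stat", "p_raw", "p_adj", "significant",
                    "prop_hydropathy") %in% names(res$pairs)))
  expect_true(all(diff(res$pairs$p_adj) >= 0))
  expect_true(all(abs(res$pairs$rho) <= 1 + 1e-12))
  td <- tidy(res)
  expect_identical(td, res$pairs)
  expect_equal(glance(res)$n_tested, nrow(res$pairs))
})

test_that("groups are maximal cliques matching brute force", {
  pairs <- tibble::tibble(site_a = c(1, 1, 2, 4), site_b = c(2, 3, 3, 5))
  g <- build_groups(pairs)
  expect_equal(g$members, list(c(1L, 2L, 3L), c(4L, 5L)))

  # a shared site may sit in two groups
  g2 <- build_groups(tibble::tibble(site_a = c(1, 2), site_b = c(2, 3)))
  expect_equal(g2$members, list(c(1L, 2L), c(2L, 3L)))

  set.seed(33)
  for (rep in 1:8) {
    n <- sample(5:10, 1)
    all_pairs <- t(combn(n, 2))
    keep <- all_pairs[runif(nrow(all_pairs)) < 0.4, , drop = FALSE]
    if (!nrow(keep)) next
    got <- build_groups(tibble::tibble(site_a = keep[, 1], site_b = keep[, 2]))
    want <- oracle_max_cliques(keep)
    expect_setequal(vapply(got$members, paste, "", collapse = "-"),
                    vapply(want, paste, "", collapse = "-"))
  }
})

test_that("property correlations behave on constructed columns", {
  aln <- protein_alignment(c(a = "IKIC", b = "AKAC", c = "IRID", d = "ARAD",
                             e = "IKIC", f = "ARAD"))
  pairs <- tibble::tibble(site_a = c(1, 1), site_b = c(3, 2))
  ann <- property_filter(pairs, aln)
  # identical columns 1 and 3 -> property correlation 1 under any scale
  expect_equal(ann$prop_hydropathy[1], 1)
  expect_equal(ann$prop_molecular_weight[1], 1)
  # hydrophobicity-coupled identical columns beat an unrelated pairing
  expect_gt(abs(ann$prop_hydropathy[1]), abs(ann$prop_hydropathy[2]))
  # invariant partner -> zero variance -> 0
  aln2 <- protein_alignment(c(a = "IA", b = "AA", c = "IA", d = "AA",
                              e = "IA", f = "AA"))
  p2 <- property_filter(tibble::tibble(site_a = 1, site_b = 2), aln2)
  expect_equal(p2$prop_hydropathy[1], 0)
})

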