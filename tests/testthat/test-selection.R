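quartet <- ape::read.tree(text = "((A:1,B:1)n1:1,(C:1,D:1)n2:1)r;")

test_that("Fitch reconstruction matches hand-worked quartet cases", {
  # invariant column: same state everywhere
  ca <- codon_alignment(matrix("ATG", 4, 2,
                               dimnames = list(c("A", "B", "C", "D"), NULL)))
  fa <- fitch_ancestors(ca, quartet)
  expect_true(all(fa$sequences == "ATG"))
  expect_equal(fa$parsimony_score, 0)

  # T,T,C,C at position 2: root ambiguous {C,T}, resolved alphabetically to C
  ca2 <- codon_alignment(matrix(c("TTT", "TTT", "TCT", "TCT"), 4, 1,
                                dimnames = list(c("A", "B", "C", "D"), NULL)))
  fa2 <- fitch_ancestors(ca2, quartet)
  root_lab <- setdiff(rownames(fa2$sequences), c("A", "B", "C", "D", "n1", "n2"))
  expect_equal(unname(fa2$sequences[root_lab, 1]), "TCT")
  expect_true(fa2$ambiguous[root_lab, 2])
  expect_equal(fa2$parsimony_score, 1)

  # tip mismatch errors
  bad <- codon_alignment(matrix("ATG", 4, 1,
                                dimnames = list(c("A", "B", "C", "E"), NULL)))
  expect_error(fitch_ancestors(bad, quartet), class = "compevo_id_error")
})

test_that("parsimony score equals exhaustive enumeration and phangorn", {
  set.seed(61)
  for (rep in 1:6) {
    tree <- ape::rtree(5)
    tree$node.label <- paste0("n", seq_len(tree$Nnode))
    codons <- matrix(random_codon_seq(6 * 5), 5, 6,
                     dimnames = list(tree$tip.label, NULL))
    codons[] <- vapply(codons, function(x) mutate_codons(x, 1), "")
    ca <- codon_alignment(codons)
    fa <- fitch_ancestors(ca, tree)
    nt <- do.call(rbind, strsplit(apply(codons, 1, paste, collapse = ""), ""))
    rownames(nt) <- rownames(codons)
    want <- sum(vapply(seq_len(ncol(nt)), function(j)
      oracle_parsimony_column(tree, setNames(nt[, j], rownames(nt))),
      numeric(1)))
    expect_equal(fa$parsimony_score, want)
    ph <- phangorn::parsimony(tree, phangorn::phyDat(nt, type = "DNA"))
    expect_equal(fa$parsimony_score, as.integer(ph))
  }
})

test_that("window classification is a pure function of its decision table", {
  a <- 0.01
  grid <- expand.grid(p_dn = c(0.001, 0.5), p_ds = c(0.001, 0.5),
                      p_low = c(0.001, 0.5), dn_gt_ds = c(TRUE, FALSE))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    ds <- 0.1; dn <- if (g$dn_gt_ds) 0.2 else 0.05
    got <- classify_window(ds, dn, g$p_dn, g$p_ds, g$p_low, alpha = a)
    want <- if (g$p_dn <= a && g$dn_gt_ds) "positive_selection"
      else if (g$p_dn <= a && g$p_ds <= a) "hotspot"
      else if (g$p_dn <= a) "accelerated_dN"
      else if (g$p_low <= a) "negative_selection"
      else "neutral"
    expect_identical(got, want)
  }
  expect_identical(classify_window(NA, 0.1, 0.5, 0.5, 0.5), "untestable")
})

scan_tree <- local({
  set.seed(99)
  tr <- ape::rtree(8)
  tr$edge.length <- rexp(nrow(tr$edge), 1 / 0.05)
  tr$node.label <- paste0("Nd", seq_len(tr$Nnode))
  tr
})

test_that("calibration is deterministic and rate-sensible", {
  c1 <- calibrate_null(scan_tree, n_codons = 50, n_sims = 20, seed = 5,
                       window_sizes = c(10, 15))
  c2 <- calibrate_null(scan_tree, n_codons = 50, n_sims = 20, seed = 5,
                       window_sizes = c(10, 15))
  expect_identical(c1$rates, c2$rates)
  expect_identical(c1$w, c2$w)
  expect_identical(c1$thresholds, c2$thresholds)
  expect_true(all(c1$rates$lambda_syn >= 0))
  # doubling branch lengths roughly doubles fitted substitution rates
  t2 <- scan_tree; t2$edge.length <- 2 * t2$edge.length
  c3 <- calibrate_null(t2, n_codons = 50, n_sims = 20, seed = 5,
                       window_sizes = c(10, 15))
  ratio <- sum(c3$rates$lambda_nonsyn) / sum(c1$rates$lambda_nonsyn)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
})

test_that("zero-length branches give zero rates", {
  t0 <- scan_tree; t0$edge.length[] <- 0
  c0 <- calibrate_null(t0, n_codons = 30, n_sims = 20, seed = 2,
                       window_sizes = 10)
  expect_true(all(c0$rates$lambda_syn == 0))
  expect_true(all(c0$rates$lambda_nonsyn == 0))
})

test_that("scan windows have correct arithmetic and neutral behaviour", {
  calib <- calibrate_null(scan_tree, n_codons = 50, n_sims = 20, seed = 5,
                          window_sizes = c(10, 15))
  sim <- simulate_alignment(sim_config(seed = 77, n_taxa = 8, n_codons = 50,
                                       tree = scan_tree))
  fa <- fitch_ancestors(sim$codon_aln, scan_tree)
  cmp <- branch_comparison(fa, fa$branches$branch[1])
  win <- scan_branch(cmp, calib)
  expect_equal(nrow(win), 50 - calib$w + 1)
  expect_true(all(win$end - win$start + 1 == calib$w))

  # identical parent/child: zero distances, never positive
  cmp0 <- cmp; cmp0$child_seq <- cmp0$parent_seq
  win0 <- scan_branch(cmp0, calib)
  expect_true(all(win0$dS == 0 & win0$dN == 0, na.rm = TRUE))
  expect_false(any(win0$classification == "positive_selection"))

  # symmetry of the underlying distance
  r1 <- li_ds_dn(cmp$parent_seq, cmp$child_seq)
  r2 <- li_ds_dn(cmp$child_seq, cmp$parent_seq)
  expect_identical(r1$dS, r2$dS)
})

test_that("a planted high-omega window is found on its branch", {
  calib <- calibrate_null(scan_tree, n_codons = 50, n_sims = 30, seed = 5)
  labels <- c(scan_tree$tip.label, scan_tree$node.label)
  branches <- labels[scan_tree$edge[, 2]]
  internal <- grepl("^Nd", branches)
  wb <- branches[internal][which.max(scan_tree$edge.length[internal])]
  hits <- 0
  for (r in 1:5) {
    sim <- simulate_alignment(sim_config(
      seed = 300 + r, n_taxa = 8, n_codons = 50, tree = scan_tree,
      planted_windows = data.frame(branch = wb, start = 18, end = 32,
                                   omega = 5)))
    sc <- scan_selection(sim$codon_aln, scan_tree, calib)
    pos <- sc$windows[sc$windows$classification == "positive_selection", ]
    hits <- hits + any(pos$branch == wb & pos$start <= 32 & pos$end >= 18)
  }
  expect_gte(hits, 4)
  expect_s3_class(tidy(scan_selection(sim$codon_aln, scan_tree, calib)),
                  "tbl_df")
})
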