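#' Simulation configuration
#'
#' Validated configuration for the codon-alignment simulator. Defaults
#' emulate a small duplication-rich gene family: a random rooted tree
#' with exponential branch lengths (mean 0.05 substitutions/site: deep
#' enough that sites substitute repeatedly, shallow enough that
#' parsimony reconstruction stays reliable), transition bias kappa = 2
#' and a moderately constrained base omega = 0.4. Planted driver sites
#' evolve at `driver_omega` (default 2, the episodic relaxed/adaptive
#' regime expected of compensating sites).
#'
#' @param seed Integer seed (all randomness derives from it).
#' @param n_taxa Number of tips (used when `tree` is NULL).
#' @param n_codons Alignment length in codons.
#' @param tree Optional `ape::phylo` (or newick); must have branch
#'   lengths. NULL draws a random topology.
#' @param branch_mean Mean of exponential branch lengths for random
#'   trees (substitutions per nucleotide site).
#' @param kappa Transition/transversion rate bias (default 2).
#' @param omega Base nonsynonymous/synonymous rate ratio (default 0.4).
#' @param planted_windows Data frame (branch, start, end, omega) of
#'   branch-specific elevated-omega codon windows.
#' @param planted_pairs Data frame (site_a, site_b, rho) of coevolving
#'   site pairs: when the driver site accepts a nonsynonymous change on a
#'   branch, the partner co-substitutes on that branch with probability
#'   rho.
#' @param n_invariant Number of invariant (never-substituting) columns.
#' @param invariant_sites Optional explicit invariant column indices.
#' @param driver_omega Omega at planted driver sites (default 2).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_taxa = 12L, n_codons = 60L, tree = NULL,
                       branch_mean = 0.05, kappa = 2, omega = 0.4,
                       planted_windows = NULL, planted_pairs = NULL,
                       n_invariant = 0L, invariant_sites = NULL,
                       driver_omega = 2) {
  stopifnot(n_taxa >= 3, n_codons >= 3, kappa > 0, omega >= 0,
            branch_mean > 0)
  if (!is.null(tree)) tree <- as_phylo(tree)
  pw <- if (is.null(planted_windows)) tibble(branch = character(),
                                             start = integer(), end = integer(),
                                             omega = numeric())
        else as_tibble(planted_windows)
  pp <- if (is.null(planted_pairs)) tibble(site_a = integer(),
                                           site_b = integer(), rho = numeric())
        else as_tibble(planted_pairs)
  if (nrow(pw) && any(pw$start < 1 | pw$end > n_codons | pw$start > pw$end))
    abort("planted window out of range")
  if (nrow(pp)) {
    sites <- c(pp$site_a, pp$site_b)
    if (any(sites < 1 | sites > n_codons) || anyDuplicated(sites))
      abort("planted pair sites must be distinct and within range")
    if (any(pp$rho < 0 | pp$rho > 1)) abort("coupling rho must be in [0, 1]")
  }
  if (!is.null(invariant_sites)) {
    n_invariant <- length(invariant_sites)
    if (any(invariant_sites < 1 | invariant_sites > n_codons))
      abort("invariant sites out of range")
  }
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 n_codons = as.integer(n_codons), tree = tree,
                 branch_mean = branch_mean, kappa = kappa, omega = omega,
                 planted_windows = pw, planted_pairs = pp,
                 n_invariant = as.integer(n_invariant),
                 invariant_sites = invariant_sites,
                 driver_omega = driver_omega),
            class = "sim_config")
}

# Mutation proposal tables: for each codon index and position, the three
# target codons and per-target type (transition?) and acceptance class.
sense_codons <- function(code = "standard") {
  tab <- codon_table(code)
  which(tab$aa != "*")
}

# Per-codon single-nucleotide mutation targets with base rates normalised
# so each nucleotide position mutates at rate 1 per unit branch length.
mutation_table <- function(tab, kappa) {
  key <- paste0("mut_", kappa)
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  target <- rate <- nonsyn <- vector("list", 64)
  for (ci in seq_len(64)) {
    if (tab$aa[ci] == "*") next
    tg <- integer(0); rt <- numeric(0); ns <- logical(0)
    for (pos in 1:3) {
      cur <- tab$pos_nt[ci, pos]
      for (ntg in setdiff(1:4, cur)) {
        cod2 <- tab$pos_nt[ci, ]; cod2[pos] <- ntg
        idx <- match(paste(NT[cod2], collapse = ""), tab$codons)
        if (tab$aa[idx] == "*") next
        tg <- c(tg, idx)
        rt <- c(rt, (if (PURINE[NT[ntg]] == PURINE[NT[cur]]) kappa else 1) /
                  (kappa + 2))
        ns <- c(ns, tab$aa[idx] != tab$aa[ci])
      }
    }
    target[[ci]] <- tg; rate[[ci]] <- rt; nonsyn[[ci]] <- ns
  }
  out <- list(target = target, rate = rate, nonsyn = nonsyn)
  .codon_env[[key]] <- out
  out
}

#' Simulate a codon alignment with planted coevolution and selection
#'
#' Gillespie process along each branch of the tree. Each codon carries a
#' rate for every single-nucleotide change: transitions weighted `kappa`,
#' transversions 1 (normalised so a neutral site accrues one expected
#' substitution per unit branch length per nucleotide position),
#' nonsynonymous targets multiplied by omega(site, branch), stops
#' excluded. Planted windows raise omega locally on one branch so that
#' omega > 1 (diversifying selection) is a genuine rate excess. Partner
#' sites of planted pairs substitute only through coupling: when the
#' driver site substitutes nonsynonymously on a branch, the partner
#' co-substitutes there with probability rho (so at rho = 1 the partner
#' changes on exactly the driver's branches). Invariant columns never
#' change.
#'
#' @param config A [sim_config()].
#' @return List: `codon_aln` ([codon_alignment()]), `protein_aln`
#'   (translated), `tree` (with node labels), `ground_truth` (list:
#'   invariant_sites, planted_pairs, planted_windows, per-branch
#'   substitution count tibble `counts` with syn/nonsyn per codon).
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "simulate_alignment"))
  tab <- codon_table("standard")
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rtree(config$n_taxa, br = NULL)
    tree$edge.length <- rexp(nrow(tree$edge), rate = 1 / config$branch_mean)
  }
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(ape::root(tree, outgroup = tree$tip.label[1],
                                    resolve.root = TRUE))
  if (is.null(tree$node.label) || !all(nzchar(tree$node.label)))
    tree$node.label <- paste0("Nd", seq_len(tree$Nnode))
  labels <- c(tree$tip.label, tree$node.label)
  ntip <- length(tree$tip.label)
  L <- config$n_codons
  inv <- config$invariant_sites
  if (is.null(inv) && config$n_invariant > 0)
    inv <- sort(sample.int(L, config$n_invariant))
  inv <- inv %||% integer(0)
  if (nrow(config$planted_pairs) &&
      any(c(config$planted_pairs$site_a, config$planted_pairs$site_b) %in% inv))
    abort("planted pair sites cannot be invariant")
  sense <- sense_codons()
  root_seq <- sample(sense, L, replace = TRUE)
  seqs <- matrix(NA_integer_, length(labels), L,
                 dimnames = list(labels, NULL))
  seqs[ntip + 1L, ] <- root_seq
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- rev(seq_len(nrow(edges)))
  counts <- list()
  kappa <- config$kappa
  gc_aa <- tab$aa
  pw <- config$planted_windows
  pp <- config$planted_pairs
  partner_sites <- if (nrow(pp)) pp$site_b else integer(0)
  mut <- mutation_table(tab, kappa)
  for (e in pre) {
    par <- edges[e, 1]; ch <- edges[e, 2]
    elen <- tree$edge.length[which(tree$edge[, 1] == par & tree$edge[, 2] == ch)]
    blab <- labels[ch]
    seq <- seqs[par, ]
    omega_site <- rep(config$omega, L)
    if (nrow(pp)) omega_site[pp$site_a] <- config$driver_omega
    if (nrow(pw)) for (q in which(pw$branch == blab))
      omega_site[pw$start[q]:pw$end[q]] <- pw$omega[q]
    omega_site[partner_sites] <- 0  # partners move only via coupling
    syn <- nonsyn <- integer(L)
    active <- setdiff(seq_len(L), inv)
    for (i in active) {
      t_rem <- elen
      repeat {
        rates <- mut$rate[[seq[i]]]
        rates[mut$nonsyn[[seq[i]]]] <- rates[mut$nonsyn[[seq[i]]]] * omega_site[i]
        lam <- sum(rates)
        if (lam <= 0) break
        t_rem <- t_rem - rexp(1, lam)
        if (t_rem <= 0) break
        pick <- sample.int(length(rates), 1, prob = rates)
        new_idx <- mut$target[[seq[i]]][pick]
        if (mut$nonsyn[[seq[i]]][pick]) nonsyn[i] <- nonsyn[i] + 1L
        else syn[i] <- syn[i] + 1L
        seq[i] <- new_idx
      }
    }
    # coupled co-substitution of planted partners on this branch; the
    # forced change avoids reverting to the pre-branch residue so the
    # planted signal is a genuine state change on that branch
    if (nrow(pp)) for (q in seq_len(nrow(pp))) {
      a <- pp$site_a[q]; b <- pp$site_b[q]
      if (nonsyn[a] > 0 && runif(1) < pp$rho[q]) {
        forced <- force_nonsyn(seq[b], tab, kappa,
                               avoid_aa = gc_aa[seqs[par, b]])
        if (!is.na(forced)) {
          seq[b] <- forced; nonsyn[b] <- nonsyn[b] + 1L
        }
      }
    }
    seqs[ch, ] <- seq
    counts[[blab]] <- tibble(branch = blab, codon = seq_len(L),
                             syn = syn, nonsyn = nonsyn)
  }
  codons <- matrix(tab$codons[seqs[seq_len(ntip), ]], ntip, L,
                   dimnames = list(tree$tip.label, NULL))
  caln <- codon_alignment(codons)
  node_codons <- matrix(tab$codons[seqs], nrow(seqs), L,
                        dimnames = list(labels, NULL))
  structure(list(codon_aln = caln, protein_aln = translate_alignment(caln),
                 tree = tree,
                 ground_truth = list(invariant_sites = inv,
                                     planted_pairs = pp,
                                     planted_windows = pw,
                                     counts = dplyr::bind_rows(counts),
                                     node_sequences = node_codons)),
            class = "simulated_alignment")
}

force_nonsyn <- function(cod_idx, tab, kappa, avoid_aa = NULL) {
  # a random accepted nonsynonymous, non-stop single-nucleotide change;
  # optionally avoiding one amino acid (e.g. the pre-branch state)
  cod <- tab$pos_nt[cod_idx, ]
  pick_from <- function(forbid) {
    cands <- integer(0); wts <- numeric(0)
    for (pos in 1:3) for (ntg in setdiff(1:4, cod[pos])) {
      cod2 <- cod; cod2[pos] <- ntg
      idx <- match(paste(NT[cod2], collapse = ""), tab$codons)
      if (tab$aa[idx] != "*" && tab$aa[idx] != tab$aa[cod_idx] &&
          !(tab$aa[idx] %in% forbid)) {
        cands <- c(cands, idx)
        wts <- c(wts, if (PURINE[NT[ntg]] == PURINE[NT[cod[pos]]]) kappa else 1)
      }
    }
    if (!length(cands)) return(NA_integer_)
    cands[sample.int(length(cands), 1, prob = wts)]
  }
  out <- pick_from(avoid_aa)
  if (is.na(out)) out <- pick_from(NULL)
  out
}

#' @export
print.simulated_alignment <- function(x, ...) {
  cat(sprintf("<simulated_alignment> %d taxa x %d codons; %d planted pairs, %d planted windows, %d invariant\n",
              length(x$codon_aln$taxa), ncol(x$codon_aln$codons),
              nrow(x$ground_truth$planted_pairs),
              nrow(x$ground_truth$planted_windows),
              length(x$ground_truth$invariant_sites)))
  invisible(x)
}

#' Simulate a toy protein structure with planted contacts
#'
#' Places residues as 3-pseudo-atom clusters on a self-avoiding chain
#' (3.8 Angstrom steps, 3.0 Angstrom clash floor), then repositions
#' planted contact pairs to min-atom distance <= 3.5 Angstrom and planted
#' mediator triples into the "within 4 Angstrom of both members, members
#' apart" geometry, keeping other planted-involved pairs >= 5 Angstrom
#' where feasible. Bounded retries; errors if the constraints cannot be
#' satisfied.
#'
#' @param n_residues Chain length.
#' @param planted_contacts 2-column matrix/data.frame of residue index
#'   pairs to place in contact.
#' @param planted_mediators 3-column matrix/data.frame (a, b, mediator):
#'   a and b are kept apart (> 4 A) with the mediator within 4 A of both.
#' @param seed Integer seed (same seed, byte-identical PDB).
#' @param path Output PDB path (NULL: temporary file).
#' @param residue_names Optional one-letter sequence for residue names
#'   (default all alanine).
#' @return List: `model` ([parse_structure()] of the written file),
#'   `path`, `ground_truth` (planted contacts/mediators).
#' @export
simulate_structure <- function(n_residues, planted_contacts = NULL,
                               planted_mediators = NULL, seed = 1L,
                               path = NULL, residue_names = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  pc <- if (is.null(planted_contacts)) matrix(integer(0), 0, 2)
        else as.matrix(planted_contacts)
  pm <- if (is.null(planted_mediators)) matrix(integer(0), 0, 3)
        else as.matrix(planted_mediators)
  if ((nrow(pc) && any(pc < 1 | pc > n_residues)) ||
      (nrow(pm) && any(pm < 1 | pm > n_residues)))
    abort("planted indices out of range")
  planted_res <- unique(c(pc, pm))
  for (attempt in 1:25) {
    set.seed(derive_seed(seed, paste0("structure", attempt)))
    centres <- chain_walk(n_residues)
    ok <- TRUE
    for (q in seq_len(nrow(pc))) {
      centres[pc[q, 2], ] <- centres[pc[q, 1], ] + 3.0 * runit()
    }
    for (q in seq_len(nrow(pm))) {
      a <- pm[q, 1]; b <- pm[q, 2]; m <- pm[q, 3]
      u <- runit()
      centres[b, ] <- centres[a, ] + 8.4 * u
      centres[m, ] <- centres[a, ] + 4.2 * u
    }
    atoms <- cluster_atoms(centres)
    # verify the planted geometry and separation of other planted pairs
    for (q in seq_len(nrow(pc)))
      if (min_dist_idx(atoms, pc[q, 1], pc[q, 2]) > 3.5) ok <- FALSE
    for (q in seq_len(nrow(pm))) {
      a <- pm[q, 1]; b <- pm[q, 2]; m <- pm[q, 3]
      if (min_dist_idx(atoms, a, b) <= 4 ||
          min_dist_idx(atoms, a, m) > 4 || min_dist_idx(atoms, b, m) > 4)
        ok <- FALSE
      # the planted mediator must be the only residue bridging a and b
      if (ok) for (r in setdiff(seq_len(n_residues), c(a, b, m))) {
        if (min_dist_idx(atoms, r, a) <= 4.3 &&
            min_dist_idx(atoms, r, b) <= 4.3) { ok <- FALSE; break }
      }
    }
    if (ok && length(planted_res) > 1) {
      planted_pairs_all <- rbind(pc, pm[, c(1, 3), drop = FALSE],
                                 pm[, c(2, 3), drop = FALSE])
      pkey <- apply(planted_pairs_all, 1, function(r) paste(sort(r), collapse = "-"))
      others <- utils::combn(sort(planted_res), 2)
      for (j in seq_len(ncol(others))) {
        key <- paste(others[, j], collapse = "-")
        if (key %in% pkey) next
        if (abs(diff(others[, j])) == 1) next  # chain neighbours
        if (min_dist_idx(atoms, others[1, j], others[2, j]) < 5) ok <- FALSE
      }
    }
    if (ok) break
  }
  if (!ok) abort("could not satisfy planted structural constraints; reduce them")
  aa3 <- if (is.null(residue_names)) rep("ALA", n_residues)
         else suppressWarnings(bio3d::aa123(residue_names))
  aa3[is.na(aa3) | aa3 == "X"] <- "ALA"
  if (is.null(path)) path <- tempfile(fileext = ".pdb")
  write_toy_pdb(atoms, aa3, path)
  model <- parse_structure(path)
  list(model = model, path = path,
       ground_truth = list(planted_contacts = pc, planted_mediators = pm))
}

runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

chain_walk <- function(n, step = 3.8, floor = 3.0) {
  centres <- matrix(0, n, 3)
  for (i in 2:n) {
    for (try in 1:200) {
      cand <- centres[i - 1, ] + step * runit()
      d <- sqrt(rowSums((centres[seq_len(i - 1), , drop = FALSE] -
                           matrix(cand, i - 1, 3, byrow = TRUE))^2))
      if (all(d >= floor)) break
    }
    centres[i, ] <- cand
  }
  centres
}

cluster_atoms <- function(centres) {
  # three pseudo-atoms per residue: centre plus two fixed-length offsets
  n <- nrow(centres)
  offs <- lapply(seq_len(n), function(i) rbind(c(0, 0, 0), 0.9 * runit(), 0.9 * runit()))
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(res = i, sweep(offs[[i]], 2, centres[i, ], `+`))))
}

min_dist_idx <- function(atoms, i, j) {
  A <- atoms[atoms[, 1] == i, -1, drop = FALSE]
  B <- atoms[atoms[, 1] == j, -1, drop = FALSE]
  min(sqrt(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)))
}

write_toy_pdb <- function(atoms, aa3, path) {
  elety <- c("CA", "CB", "CG")
  lines <- character(nrow(atoms))
  for (r in seq_len(nrow(atoms))) {
    res <- atoms[r, 1]
    k <- ((r - 1) %% 3) + 1
    lines[r] <- sprintf(
      "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      r, elety[k], aa3[res], res, atoms[r, 2], atoms[r, 3], atoms[r, 4])
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Build the bundled deterministic toy fixture
#'
#' A complete small dataset with known ground truth: 12 taxa, 60 codons,
#' two planted coevolving pairs (one in structural contact, one mediated
#' by a planted invariant site), one planted omega = 5 window of 15
#' codons on an internal branch, three invariant columns, and a toy
#' structure realising the planted geometry. Regenerating with the same
#' seed gives identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed (default 47).
#' @return List: file paths (`protein_fasta`, `cds_fasta`, `tree`,
#'   `pdb`, `regions`, `ground_truth`) plus the in-memory objects
#'   (`sim`, `structure`, `regions`, `truth`).
#' @export
make_fixture <- function(dir = tempfile("toy-ang"), seed = 47L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_codons <- 60L
  contact_pair <- c(12L, 27L)
  mediated_pair <- c(20L, 44L)
  mediator <- 33L
  invariant <- c(mediator, 7L, 52L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "fixture_tree"))
  tree <- ape::rtree(12)
  tree$edge.length <- rexp(nrow(tree$edge), 1 / 0.05)
  tree$node.label <- paste0("Nd", seq_len(tree$Nnode))
  # plant the window on the longest internal branch (enough substitution
  # opportunity for the scan while keeping a multi-tip clade below it)
  labels <- c(tree$tip.label, tree$node.label)
  branch_of <- labels[tree$edge[, 2]]
  parent_of <- labels[tree$edge[, 1]]
  # root-adjacent branches are excluded: without an outgroup, parsimony
  # cannot polarise changes across the root, so they are untestable
  internal <- grepl("^Nd", branch_of) & parent_of != tree$node.label[1]
  wbranch <- branch_of[internal][which.max(tree$edge.length[internal])]
  cfg <- sim_config(seed = seed, n_taxa = 12L, n_codons = n_codons,
                    tree = tree,
                    planted_windows = tibble(branch = wbranch, start = 2L,
                                             end = 16L, omega = 5),
                    planted_pairs = tibble(site_a = c(contact_pair[1], mediated_pair[1]),
                                           site_b = c(contact_pair[2], mediated_pair[2]),
                                           rho = c(0.9, 0.9)),
                    invariant_sites = invariant)
  sim <- simulate_alignment(cfg)
  ref <- sim$protein_aln$taxa[1]
  st <- simulate_structure(
    n_codons,
    planted_contacts = rbind(contact_pair),
    planted_mediators = rbind(c(mediated_pair, mediator)),
    seed = seed, path = file.path(dir, "structure.pdb"),
    residue_names = sim$protein_aln$mat[ref, ])
  regions <- list(active_site = c(13L, 40L), B1 = 44L, P2 = c(5L, 8L),
                  NLS = 31:35)
  paths <- list(protein_fasta = file.path(dir, "protein.fasta"),
                cds_fasta = file.path(dir, "cds.fasta"),
                tree = file.path(dir, "tree.nwk"),
                pdb = st$path,
                regions = file.path(dir, "regions.json"),
                ground_truth = file.path(dir, "ground_truth.json"))
  write_fasta(sim$protein_aln, paths$protein_fasta)
  write_fasta(sim$codon_aln, paths$cds_fasta)
  ape::write.tree(sim$tree, paths$tree)
  write_regions(regions, paths$regions)
  gt <- list(ref_taxon = ref,
             contact_pair = contact_pair, mediated_pair = mediated_pair,
             mediator = mediator, invariant_sites = invariant,
             planted_window = list(branch = wbranch, start = 2L, end = 16L,
                                   omega = 5),
             planted_pairs = as.data.frame(cfg$planted_pairs))
  jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(paths, list(sim = sim, structure = st, regions = regions,
                truth = gt))
}
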