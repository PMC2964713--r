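NT_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)
BIT_NT <- c("A", "C", "G", "T")  # bit 1,2,4,8 -> alphabetical order

nt_to_bits <- function(ch) {
  b <- NT_BITS[ch]
  b[is.na(b)] <- 15L  # gap/ambiguity: any nucleotide
  unname(b)
}

lowest_bit_nt <- function(bits) BIT_NT[match(bitwAnd(bits, -bits), c(1L, 2L, 4L, 8L))]

#' Ancestral codon sequences by Fitch parsimony
#'
#' Nucleotide-level Fitch parsimony on a rooted binary tree: bottom-up
#' state sets, then top-down resolution with ties broken by alphabetical
#' nucleotide order. Arbitrarily resolved positions are flagged ambiguous
#' and excluded from downstream substitution counts.
#'
#' @param codon_aln A [codon_alignment()].
#' @param tree An `ape::phylo` tree (or newick file/string); tips must
#'   match alignment taxa exactly. Multifurcations are resolved with
#'   [ape::multi2di()].
#' @return Object of class `fitch_ancestors`: list with `sequences`
#'   (codon matrix for all nodes, tips included, rownames = node labels),
#'   `ambiguous` (logical matrix nodes x nucleotide positions),
#'   `tree` (with internal node labels `Nd<k>` where absent), `branches`
#'   (tibble: branch = child label, parent label, length),
#'   `parsimony_score` (total Fitch changes).
#' @export
fitch_ancestors <- function(codon_aln, tree) {
  tree <- as_phylo(tree)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(ape::root(tree, outgroup = tree$tip.label[1],
                                    resolve.root = TRUE))
  extra <- setdiff(tree$tip.label, codon_aln$taxa)
  miss <- setdiff(codon_aln$taxa, tree$tip.label)
  if (length(extra) || length(miss))
    abort(sprintf("tip/taxon mismatch. tree-only: %s; alignment-only: %s",
                  paste(extra, collapse = ",") %||% "",
                  paste(miss, collapse = ",") %||% ""),
          class = "compevo_id_error")
  if (is.null(tree$node.label) || !all(nzchar(tree$node.label)))
    tree$node.label <- paste0("Nd", seq_len(tree$Nnode))
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  L3 <- ncol(codon_aln$codons) * 3L
  nt <- t(vapply(tree$tip.label, function(tx)
    strsplit(paste(codon_aln$codons[tx, ], collapse = ""), "")[[1]],
    character(L3)))
  sets <- matrix(0L, ntot, L3)
  sets[seq_len(ntip), ] <- t(apply(nt, 1, nt_to_bits))
  score <- 0L
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  # bottom-up: combine the two children of each internal node
  for (node in unique(edges[, 1])) {
    ch <- edges[edges[, 1] == node, 2]
    s <- sets[ch[1], ]
    for (k in ch[-1]) {
      inter <- bitwAnd(s, sets[k, ])
      un <- bitwOr(s, sets[k, ])
      use_union <- inter == 0L
      score <- score + sum(use_union)
      s <- ifelse(use_union, un, inter)
    }
    sets[node, ] <- s
  }
  states <- matrix(NA_character_, ntot, L3)
  states[seq_len(ntip), ] <- nt
  ambig <- matrix(FALSE, ntot, L3)
  root <- ntip + 1L
  multi <- bitwAnd(sets[root, ], sets[root, ] - 1L) != 0L
  states[root, ] <- lowest_bit_nt(sets[root, ])
  ambig[root, ] <- multi
  for (e in rev(seq_len(nrow(edges)))) {  # preorder
    par <- edges[e, 1]; ch <- edges[e, 2]
    if (ch <= ntip) next
    pb <- NT_BITS[states[par, ]]
    inherits_ok <- bitwAnd(sets[ch, ], pb) != 0L
    states[ch, ] <- ifelse(inherits_ok, states[par, ], lowest_bit_nt(sets[ch, ]))
    multi <- bitwAnd(sets[ch, ], sets[ch, ] - 1L) != 0L
    ambig[ch, ] <- !inherits_ok & multi
  }
  labels <- c(tree$tip.label, tree$node.label)
  rownames(states) <- rownames(ambig) <- labels
  ncod <- L3 / 3L
  seqs <- vapply(seq_len(ncod), function(i)
    paste0(states[, 3 * i - 2], states[, 3 * i - 1], states[, 3 * i]),
    character(ntot))
  if (!is.matrix(seqs)) seqs <- matrix(seqs, nrow = ntot)
  rownames(seqs) <- labels
  # tips keep their gap triplets verbatim
  seqs[seq_len(ntip), ] <- codon_aln$codons[tree$tip.label, ]
  branches <- tibble(branch = labels[tree$edge[, 2]],
                     parent = labels[tree$edge[, 1]],
                     length = tree$edge.length %||% rep(NA_real_, nrow(tree$edge)))
  structure(list(sequences = seqs, ambiguous = ambig, tree = tree,
                 branches = branches, parsimony_score = score),
            class = "fitch_ancestors")
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && file.exists(tree)) return(ape::read.tree(tree))
  if (is.character(tree)) return(ape::read.tree(text = tree))
  abort("tree must be a phylo object, newick file or newick string")
}

#' @export
print.fitch_ancestors <- function(x, ...) {
  cat(sprintf("<fitch_ancestors> %d nodes, parsimony score %d\n",
              nrow(x$sequences), x$parsimony_score))
  invisible(x)
}

#' Parent/child codon sequences for one branch
#'
#' @param fa A [fitch_ancestors()] result.
#' @param branch Branch id (child node label).
#' @param code Genetic code id.
#' @param mask_ambiguous Exclude codons whose reconstruction involved an
#'   arbitrarily resolved (ambiguous) nucleotide at either end (default
#'   TRUE, as the selection scan requires; coevolution profiling keeps
#'   them, accepting the deterministic resolution).
#' @return List with `branch`, `parent_seq`, `child_seq` (codon vectors)
#'   and `usable` (logical per codon: no gap, no stop, and optionally no
#'   arbitrary Fitch resolution, in either sequence).
#' @export
branch_comparison <- function(fa, branch, code = "standard",
                              mask_ambiguous = TRUE) {
  i <- match(branch, fa$branches$branch)
  if (is.na(i)) abort(sprintf("unknown branch: %s", branch))
  par <- fa$branches$parent[i]
  ps <- fa$sequences[par, ]; cs <- fa$sequences[branch, ]
  ncod <- length(ps)
  amb <- fa$ambiguous[par, ] | fa$ambiguous[branch, ]
  amb_codon <- if (mask_ambiguous)
    vapply(seq_len(ncod), function(k) any(amb[(3 * k - 2):(3 * k)]),
           logical(1))
  else rep(FALSE, ncod)
  gc <- genetic_code(code)
  ok <- !amb_codon & ps %in% names(gc) & cs %in% names(gc)
  ok[ok] <- gc[ps[ok]] != "*" & gc[cs[ok]] != "*"
  list(branch = branch, parent_seq = ps, child_seq = cs, usable = ok)
}

# Substitution counts per codon for one branch: nucleotide differences,
# classed synonymous/nonsynonymous by whether the amino acid changed.
branch_codon_counts <- function(cmp, code = "standard") {
  gc <- genetic_code(code)
  ncod <- length(cmp$parent_seq)
  syn <- nonsyn <- integer(ncod)
  idx <- which(cmp$usable & cmp$parent_seq != cmp$child_seq)
  for (k in idx) {
    nd <- sum(strsplit(cmp$parent_seq[k], "")[[1]] !=
                strsplit(cmp$child_seq[k], "")[[1]])
    if (gc[cmp$parent_seq[k]] == gc[cmp$child_seq[k]]) syn[k] <- nd
    else nonsyn[k] <- nd
  }
  tibble(codon = seq_len(ncod), syn = syn, nonsyn = nonsyn,
         usable = cmp$usable)
}

#' Calibrate the sliding-window null from neutral simulations
#'
#' Simulates `n_sims` alignments on the input tree under the base model
#' (no planted windows or pairs), reconstructs ancestral sequences, and
#' fits per-branch Poisson rates of synonymous and nonsynonymous
#' substitutions per codon. For every candidate window size the
#' distribution over simulations of the smallest window p-value (across
#' all branches and windows) is recorded, and the familywise
#' significance threshold is set just below its minimum, so a fully
#' neutral alignment produces a significant window with probability of
#' about 1/(n_sims+1). Among the window sizes whose false-positive
#' fraction under their own threshold is at most `alpha` (all of them,
#' by construction), the one needing the smallest per-codon substitution
#' excess for a call — the most sensitive — is selected; ties go to the
#' smallest window.
#'
#' @param tree `ape::phylo` with branch lengths (the scan tree).
#' @param n_codons Alignment length used for the simulations.
#' @param n_sims Number of neutral simulations (>= 20).
#' @param seed Integer seed.
#' @param alpha Significance level (default 0.01).
#' @param window_sizes Candidate window sizes in codons (default 5:25).
#' @param kappa,omega Simulator parameters (see [sim_config()]).
#' @return Object of class `null_calibration`: list with `rates` tibble
#'   (branch, lambda_syn, lambda_nonsyn per codon), `w` (chosen window),
#'   `thresholds` (named vector: p_dN upper, p_dS upper, p_dN lower
#'   familywise thresholds at the chosen w), `window_fp` tibble (w,
#'   fp_fraction under the calibrated threshold, sensitivity =
#'   substitutions per codon needed for a call), `alpha`, `n_sims`,
#'   `seed`.
#' @export
calibrate_null <- function(tree, n_codons, n_sims = 50, seed = 1L,
                           alpha = 0.01, window_sizes = 5:25,
                           kappa = 2, omega = 0.4) {
  if (n_sims < 20) abort("n_sims must be >= 20")
  tree <- as_phylo(tree)
  per_sim <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    sim <- simulate_alignment(sim_config(
      seed = derive_seed(seed, paste0("calib", s)),
      n_taxa = length(tree$tip.label), n_codons = n_codons, tree = tree,
      kappa = kappa, omega = omega))
    fa <- fitch_ancestors(sim$codon_aln, sim$tree)
    per_sim[[s]] <- lapply(setNames(nm = fa$branches$branch), function(b)
      branch_codon_counts(branch_comparison(fa, b)))
  }
  branches <- names(per_sim[[1]])
  rates <- dplyr::bind_rows(lapply(branches, function(b) {
    syn <- vapply(per_sim, function(x) sum(x[[b]]$syn), numeric(1))
    non <- vapply(per_sim, function(x) sum(x[[b]]$nonsyn), numeric(1))
    tibble(branch = b, lambda_syn = mean(syn) / n_codons,
           lambda_nonsyn = mean(non) / n_codons)
  }))
  lam_n <- setNames(rates$lambda_nonsyn, rates$branch)
  lam_s <- setNames(rates$lambda_syn, rates$branch)
  minp <- function(counts, lam, w, lower = FALSE) {
    out <- 1
    for (b in branches) {
      cnt <- counts[[b]]$nonsyn
      if (length(cnt) < w) next
      wsum <- cumsum_window(cnt, w)
      p <- if (lower) ppois(wsum, lam[b] * w)
           else ppois(wsum - 1, lam[b] * w, lower.tail = FALSE)
      out <- min(out, p)
    }
    out
  }
  minp_s <- function(counts, w) {
    out <- 1
    for (b in branches) {
      cnt <- counts[[b]]$syn
      if (length(cnt) < w) next
      wsum <- cumsum_window(cnt, w)
      out <- min(out, ppois(wsum - 1, lam_s[b] * w, lower.tail = FALSE))
    }
    out
  }
  eval_w <- function(w) {
    up <- vapply(per_sim, minp, numeric(1), lam = lam_n, w = w)
    ds <- vapply(per_sim, minp_s, numeric(1), w = w)
    low <- vapply(per_sim, minp, numeric(1), lam = lam_n, w = w, lower = TRUE)
    thr <- c(up = 0.999 * min(up), ds = 0.999 * min(ds),
             low = 0.999 * min(low))
    fp <- mean(up <= thr["up"])
    # substitutions per codon an average branch needs for a positive call
    need <- vapply(branches, function(b) {
      k <- qpois(thr[["up"]], lam_n[b] * w, lower.tail = FALSE) + 1
      k / w
    }, numeric(1))
    list(thr = thr, fp = fp, sens = stats::median(need))
  }
  evals <- lapply(window_sizes, eval_w)
  fp <- vapply(evals, `[[`, numeric(1), "fp")
  sens <- vapply(evals, `[[`, numeric(1), "sens")
  ok <- which(fp <= alpha)
  if (!length(ok)) {
    ok <- length(window_sizes)
    warn("no candidate window size met the false-positive criterion; largest used")
  }
  pick <- ok[order(sens[ok], window_sizes[ok])][1]
  structure(list(rates = rates, w = window_sizes[pick],
                 thresholds = evals[[pick]]$thr,
                 window_fp = tibble(w = window_sizes, fp_fraction = fp,
                                    sensitivity = sens),
                 alpha = alpha, n_sims = n_sims, seed = seed),
            class = "null_calibration")
}

cumsum_window <- function(x, w) {
  cs <- cumsum(x)
  cs[w:length(x)] - c(0, cs[seq_len(length(x) - w)])
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf("<null_calibration> window w = %d codons, %d branches, %d sims\n",
              x$w, nrow(x$rates), x$n_sims))
  invisible(x)
}

#' Classify one window from its statistics
#'
#' Pure decision table. `p_dn`/`p_ds` are upper-tail Poisson
#' probabilities of the observed nonsynonymous/synonymous counts under
#' the calibrated rates, `p_dn_low` the lower tail. The thresholds
#' default to `alpha`; the scan passes the familywise-calibrated ones.
#'
#' @param ds,dn Window distances (substitutions/site); NA = untestable.
#' @param p_dn,p_ds,p_dn_low Tail probabilities.
#' @param alpha Significance level.
#' @param alpha_dn,alpha_ds,alpha_low Per-tail thresholds (default
#'   `alpha`).
#' @return One of `positive_selection`, `hotspot`, `accelerated_dN`,
#'   `negative_selection`, `neutral`, `untestable`.
#' @export
classify_window <- function(ds, dn, p_dn, p_ds, p_dn_low, alpha = 0.01,
                            alpha_dn = alpha, alpha_ds = alpha,
                            alpha_low = alpha) {
  if (anyNA(c(ds, dn, p_dn, p_ds, p_dn_low))) return("untestable")
  if (p_dn <= alpha_dn && dn > ds) return("positive_selection")
  if (p_dn <= alpha_dn && p_ds <= alpha_ds) return("hotspot")
  if (p_dn <= alpha_dn) return("accelerated_dN")
  if (p_dn_low <= alpha_low) return("negative_selection")
  "neutral"
}

#' Sliding-window selection scan on one branch
#'
#' Slides a `calib$w`-codon window (step 1) along the branch's
#' parent/child comparison. Each window reports Li-method dS/dN, omega
#' (flagged `inf` when dS = 0 and dN > 0), Poisson tail probabilities of
#' the substitution counts against the branch's calibrated per-window
#' expectations and the [classify_window()] call at the calibration's
#' familywise thresholds.
#'
#' @param comparison A [branch_comparison()].
#' @param calib A [calibrate_null()] result.
#' @param alpha Significance level override (default: the calibrated
#'   thresholds).
#' @param code Genetic code id.
#' @return Tibble: branch, start, end, n_usable, obs_syn, obs_nonsyn,
#'   dS, dN, omega, omega_flag, p_dN, p_dS, p_dN_low, classification.
#' @export
scan_branch <- function(comparison, calib, alpha = NULL, code = "standard") {
  thr <- calib$thresholds
  if (!is.null(alpha)) thr <- c(up = alpha, ds = alpha, low = alpha)
  w <- calib$w
  ncod <- length(comparison$parent_seq)
  if (w > ncod) abort("window larger than alignment", class = "compevo_length_error")
  r <- calib$rates[calib$rates$branch == comparison$branch, ]
  if (!nrow(r)) abort(sprintf("branch %s not in calibration", comparison$branch))
  cnt <- branch_codon_counts(comparison, code)
  # full-length per-codon Li count profiles (zero rows at unusable codons)
  Lm <- tsm <- tvm <- matrix(0, ncod, 3)
  prof <- tryCatch(codon_pair_counts(comparison$parent_seq,
                                     comparison$child_seq, code),
                   compevo_degenerate_error = function(e) NULL)
  if (!is.null(prof)) {
    keep <- prof$which[cnt$usable[prof$which]]
    sel <- match(keep, prof$which)
    Lm[keep, ] <- prof$L[sel, , drop = FALSE]
    tsm[keep, ] <- prof$ts[sel, , drop = FALSE]
    tvm[keep, ] <- prof$tv[sel, , drop = FALSE]
  }
  starts <- seq_len(ncod - w + 1)
  syn_w <- cumsum_window(cnt$syn, w)
  non_w <- cumsum_window(cnt$nonsyn, w)
  use_w <- cumsum_window(as.integer(cnt$usable), w)
  Lw <- apply(Lm, 2, cumsum_window, w = w)
  tsw <- apply(tsm, 2, cumsum_window, w = w)
  tvw <- apply(tvm, 2, cumsum_window, w = w)
  if (length(starts) == 1) {
    Lw <- matrix(Lw, 1); tsw <- matrix(tsw, 1); tvw <- matrix(tvw, 1)
  }
  out <- lapply(starts, function(st) {
    k <- st
    n_use <- use_w[k]
    if (n_use == 0)
      return(tibble(branch = comparison$branch, start = st, end = st + w - 1,
                    n_usable = 0L, obs_syn = NA_integer_, obs_nonsyn = NA_integer_,
                    dS = NA_real_, dN = NA_real_, omega = NA_real_,
                    omega_flag = NA_character_, p_dN = NA_real_, p_dS = NA_real_,
                    p_dN_low = NA_real_, classification = "untestable"))
    li <- li_from_counts(Lw[k, ], tsw[k, ], tvw[k, ], n_codons = n_use)
    ds <- if (li$saturated) NA_real_ else li$dS
    dn <- if (li$saturated) NA_real_ else li$dN
    # expectation on the full window, exactly as calibrated (the fitted
    # per-codon rates already absorb the ambiguity-masking process)
    lam_n <- r$lambda_nonsyn * w
    lam_s <- r$lambda_syn * w
    p_dn <- ppois(non_w[k] - 1, lam_n, lower.tail = FALSE)
    p_ds <- ppois(syn_w[k] - 1, lam_s, lower.tail = FALSE)
    p_dn_low <- ppois(non_w[k], lam_n)
    tibble(branch = comparison$branch, start = st, end = st + w - 1,
           n_usable = as.integer(n_use), obs_syn = as.integer(syn_w[k]),
           obs_nonsyn = as.integer(non_w[k]), dS = ds, dN = dn,
           omega = li$omega, omega_flag = li$omega_flag,
           p_dN = p_dn, p_dS = p_ds, p_dN_low = p_dn_low,
           classification = classify_window(ds, dn, p_dn, p_ds, p_dn_low,
                                            alpha_dn = thr[["up"]],
                                            alpha_ds = thr[["ds"]],
                                            alpha_low = thr[["low"]]))
  })
  dplyr::bind_rows(out)
}

#' Scan every branch of a tree
#'
#' Reconstructs ancestral sequences with [fitch_ancestors()] and runs
#' [scan_branch()] on each branch of the tree.
#'
#' @param codon_aln A [codon_alignment()].
#' @param tree Tree (see [fitch_ancestors()]).
#' @param calib A [calibrate_null()] result for the same tree.
#' @param alpha Optional override of the calibrated familywise window
#'   thresholds (NULL, the default, uses them).
#' @return Object of class `selection_scan`: list with `windows` (bound
#'   [scan_branch()] tibbles), `calib`, `alpha`.
#' @export
scan_selection <- function(codon_aln, tree, calib, alpha = NULL) {
  fa <- fitch_ancestors(codon_aln, tree)
  win <- dplyr::bind_rows(lapply(fa$branches$branch, function(b)
    scan_branch(branch_comparison(fa, b), calib, alpha)))
  structure(list(windows = win, calib = calib,
                 alpha = alpha %||% calib$alpha, fitch = fa),
            class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  tab <- table(x$windows$classification)
  cat(sprintf("<selection_scan> %d windows over %d branches (w = %d)\n",
              nrow(x$windows), length(unique(x$windows$branch)), x$calib$w))
  print(tab)
  invisible(x)
}

#' @export
tidy.selection_scan <- function(x, ...) x$windows

#' @export
glance.selection_scan <- function(x, ...) {
  tibble(n_windows = nrow(x$windows),
         n_branches = length(unique(x$windows$branch)),
         w = x$calib$w, alpha = x$alpha,
         n_positive = sum(x$windows$classification == "positive_selection"))
}

#' @export
autoplot.selection_scan <- function(object, ...) {
  df <- object$windows[object$windows$classification != "untestable", ]
  df$mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = -log10(pmax(.data$p_dN, 1e-16)),
                                   colour = .data$classification)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~branch) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::labs(x = "window midpoint (codon)", y = "-log10 p(dN)") +
    ggplot2::theme_minimal()
}

#' Write scan windows as TSV
#'
#' @param scan A [scan_selection()] result (or windows tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  df <- if (inherits(scan, "selection_scan")) scan$windows else scan
  df$omega_or_flag <- ifelse(is.na(df$omega), df$omega_flag, format(df$omega))
  write.table(df[, c("branch", "start", "end", "dS", "dN", "omega_or_flag",
                     "p_dN", "p_dS", "classification")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
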