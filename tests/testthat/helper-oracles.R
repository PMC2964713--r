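# Independent oracles: brute-force implementations kept deliberately
# separate from the package's code paths.

# Fraction of differing sequence pairs at one column, by explicit O(n^2)
# enumeration.
oracle_pair_diff <- function(column) {
  res <- column[!column %in% c("-", "X")]
  n <- length(res)
  if (n < 2) return(NA_real_)
  diff <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (res[i] != res[j]) diff <- diff + 1
  }
  diff / tot
}

# Degeneracy class of one codon position, derived directly from the
# standard genetic code by string substitution.
oracle_degeneracy <- function(codon, pos) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  nts <- c("A", "C", "G", "T")
  cur <- substr(codon, pos, pos)
  nsyn <- 0
  for (nt in setdiff(nts, cur)) {
    mut <- codon
    substr(mut, pos, pos) <- nt
    if (gc[[mut]] == aa) nsyn <- nsyn + 1
  }
  if (nsyn == 3) 4 else if (nsyn == 0) 0 else 2
}

# Li (1993) dS/dN by per-codon degeneracy-table counting written as a
# plain double loop, with the Kimura two-parameter corrections inlined.
oracle_li <- function(codons1, codons2) {
  gc <- Biostrings::GENETIC_CODE
  is_purine <- function(x) x %in% c("A", "G")
  L <- c(`0` = 0, `2` = 0, `4` = 0)
  ts <- tv <- c(`0` = 0, `2` = 0, `4` = 0)
  for (k in seq_along(codons1)) {
    c1 <- codons1[k]; c2 <- codons2[k]
    if (is.na(gc[c1]) || is.na(gc[c2])) next
    if (gc[[c1]] == "*" || gc[[c2]] == "*") next
    for (pos in 1:3) {
      d1 <- as.character(oracle_degeneracy(c1, pos))
      d2 <- as.character(oracle_degeneracy(c2, pos))
      L[d1] <- L[d1] + 0.5
      L[d2] <- L[d2] + 0.5
      n1 <- substr(c1, pos, pos); n2 <- substr(c2, pos, pos)
      if (n1 != n2) {
        if (is_purine(n1) == is_purine(n2)) {
          ts[d1] <- ts[d1] + 0.5; ts[d2] <- ts[d2] + 0.5
        } else {
          tv[d1] <- tv[d1] + 0.5; tv[d2] <- tv[d2] + 0.5
        }
      }
    }
  }
  k2p <- function(P, Q) {
    P <- unname(P); Q <- unname(Q)
    a <- 1 - 2 * P - Q; b <- 1 - 2 * Q
    if (a <= 0 || b <= 0) return(c(A = NA_real_, B = NA_real_))
    c(A = -0.5 * log(a) + 0.25 * log(b), B = -0.5 * log(b))
  }
  kk <- lapply(c("0", "2", "4"), function(cl) {
    if (L[cl] == 0) return(c(A = 0, B = 0))
    k2p(ts[cl] / L[cl], tv[cl] / L[cl])
  })
  names(kk) <- c("0", "2", "4")
  dS <- (L["2"] * kk[["2"]]["A"] + L["4"] * kk[["4"]]["A"]) /
    (L["2"] + L["4"]) + kk[["4"]]["B"]
  dN <- (L["0"] * kk[["0"]]["B"] + L["2"] * kk[["2"]]["B"]) /
    (L["0"] + L["2"]) + kk[["0"]]["A"]
  list(dS = unname(dS), dN = unname(dN))
}

# Mean and minimum inter-atom distance by naive double loops.
oracle_mean_dist <- function(A, B) {
  tot <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    tot <- tot + sqrt(sum((A[i, ] - B[j, ])^2))
  tot / (nrow(A) * nrow(B))
}
oracle_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

# Maximal cliques (size >= 2) by exhaustive subset enumeration, n <= 12.
oracle_max_cliques <- function(edges, nodes = sort(unique(as.vector(edges)))) {
  n <- length(nodes)
  stopifnot(n <= 12)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    a <- as.character(edges[r, 1]); b <- as.character(edges[r, 2])
    adj[a, b] <- adj[b, a] <- TRUE
  }
  is_clique <- function(members) {
    if (length(members) < 2) return(FALSE)
    m <- as.character(members)
    all(adj[m, m][upper.tri(diag(length(m)))])
  }
  cliques <- list()
  for (mask in seq_len(2^n - 1)) {
    members <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (is_clique(members)) cliques[[length(cliques) + 1]] <- members
  }
  maximal <- Filter(function(cl) {
    !any(vapply(cliques, function(other)
      length(other) > length(cl) && all(cl %in% other), logical(1)))
  }, cliques)
  unique(lapply(maximal, function(m) sort(as.integer(m))))
}

# Minimum Fitch changes for one nucleotide column by exhaustive
# enumeration of internal-node labelings (small trees only).
oracle_parsimony_column <- function(tree, states) {
  nts <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  stopifnot(nint <= 6)
  combos <- expand.grid(rep(list(nts), nint), stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    lab <- c(states[tree$tip.label], unlist(combos[r, ]))
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

random_codon_seq <- function(n, rng) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  sample(sense, n, replace = TRUE)
}

# Mutate a codon vector with k random single-nucleotide, non-stop changes.
mutate_codons <- function(codons, k) {
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  for (q in seq_len(k)) {
    repeat {
      i <- sample(length(codons), 1)
      pos <- sample(3, 1)
      nt <- sample(setdiff(nts, substr(codons[i], pos, pos)), 1)
      mut <- codons[i]
      substr(mut, pos, pos) <- nt
      if (gc[[mut]] != "*") { codons[i] <- mut; break }
    }
  }
  codons
}

# all permutations of 1..n (tiny n), avoiding extra dependencies
gtools_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}
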