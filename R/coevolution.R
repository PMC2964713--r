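#' Default physico-chemical residue scales
#'
#' Kyte-Doolittle hydropathy and residue molecular weight (Da), used by
#' [property_filter()] to ask whether correlated substitutions also track
#' each other in chemistry, not just in rate.
#'
#' @return Named list of named numeric vectors over the 20 residues.
#' @export
default_property_scales <- function() {
  list(
    hydropathy = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2),
    molecular_weight = c(A = 89.09, R = 174.2, N = 132.12, D = 133.1,
                         C = 121.16, Q = 146.15, E = 147.13, G = 75.07,
                         H = 155.16, I = 131.17, L = 131.17, K = 146.19,
                         M = 149.21, F = 165.19, P = 115.13, S = 105.09,
                         T = 119.12, W = 204.23, Y = 181.19, V = 117.15))
}

# Sequence-pair index (k < l) for an n-taxa alignment.
seq_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
}

#' Divergence-corrected substitution-score residuals
#'
#' The building block of the coevolution statistic. For site i and
#' sequence pair (k, l), the transition score is the substitution-matrix
#' score of the residue pair at i divided by the pair's synonymous
#' divergence t_kl (proxy for divergence time). Because the 1/t_kl
#' correction is shared by every site, each sequence pair's mean score
#' over sites is removed first (otherwise all site pairs correlate
#' through divergence time alone); the residual D_i(kl) then also
#' subtracts the site mean, so every site's residual vector is centred.
#' Pairs where either residue is a gap or `X` are NA.
#'
#' @param aln A [protein_alignment()].
#' @param t A [pairwise_synonymous_distance()] result (or symmetric
#'   numeric matrix with taxa dimnames).
#' @param matrix Substitution matrix id/path/matrix (default BLOSUM62).
#' @return List with `D` (n_seq_pairs x n_sites residual matrix), `pairs`
#'   (two-column index of sequence pairs), `informative` (logical per
#'   site: >= 2 distinct non-gap residues), `n_nongap` per site.
#' @export
caps_residuals <- function(aln, t, matrix = "BLOSUM62") {
  B <- substitution_matrix(matrix)
  tm <- if (inherits(t, "pair_divergence")) t$t else t
  if (!all(aln$taxa %in% rownames(tm)))
    abort("divergence matrix lacks alignment taxa", class = "compevo_id_error")
  tm <- tm[aln$taxa, aln$taxa]
  n <- length(aln$taxa)
  sp <- seq_pairs(n)
  tvec <- tm[sp]
  S <- aln$length
  theta <- matrix(NA_real_, nrow(sp), S)
  informative <- logical(S)
  n_nongap <- integer(S)
  for (i in seq_len(S)) {
    col <- aln$mat[, i]
    usable <- !col %in% c("-", "X")
    n_nongap[i] <- sum(usable)
    informative[i] <- length(unique(col[usable])) >= 2
    ok <- usable[sp[, 1]] & usable[sp[, 2]]
    if (!any(ok)) next
    theta[ok, i] <- B[cbind(col[sp[ok, 1]], col[sp[ok, 2]])] / tvec[ok]
  }
  # remove the shared divergence-time trend (per-pair mean over sites),
  # then centre each site's vector
  pair_effect <- rowMeans(theta, na.rm = TRUE)
  D <- theta - pair_effect
  D <- sweep(D, 2, colMeans(D, na.rm = TRUE))
  n_states <- vapply(seq_len(S), function(i) {
    col <- aln$mat[, i]
    length(unique(col[!col %in% c("-", "X")]))
  }, integer(1))
  list(D = D, pairs = sp, informative = informative, n_states = n_states,
       n_nongap = n_nongap, taxa = aln$taxa)
}

cor_masked <- function(x, y, min_pairs = 6L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

#' Coevolution correlation for one site pair
#'
#' Pearson correlation of the divergence-corrected score residuals of two
#' sites across sequence pairs (shared non-gap pairs only). A site with
#' zero residual variance — in particular an invariant column — yields 0.
#'
#' @param aln A [protein_alignment()].
#' @param t Pair divergence (see [caps_residuals()]).
#' @param site_a,site_b Column indices.
#' @param matrix Substitution matrix.
#' @param min_pairs Minimum shared sequence pairs (default 6); below it
#'   the pair is untestable and NA is returned.
#' @return Correlation in \[-1, 1\], 0 under the zero-variance rule, or NA
#'   if untestable.
#' @export
caps_correlation <- function(aln, t, site_a, site_b, matrix = "BLOSUM62",
                             min_pairs = 6L) {
  r <- caps_residuals(aln, t, matrix)
  # invariant columns carry no substitution signal: zero-variance rule
  if (!r$informative[site_a] || !r$informative[site_b]) return(0)
  cor_masked(r$D[, site_a], r$D[, site_b], min_pairs)
}

#' Per-branch substitution-rate profiles for coevolution detection
#'
#' Reconstructs ancestral sequences by Fitch parsimony and scores, for
#' every branch and alignment site, whether the amino acid changed
#' (`score = "binary"`, the default) or the magnitude of change (`score
#' = "blosum"`: square root of the BLOSUM dissimilarity `b(p,p) +
#' b(c,c) - 2 b(p,c)` between parent and child residues). The indicator
#' score is the default because the covariance of indicator profiles
#' counts co-substitution branches, whereas exchange-score magnitudes
#' are heterogeneous enough that one large chance coincidence can match
#' several coupled events. The mean change score of each branch across
#' sites is then removed — the divergence
#' correction: branches representing more evolutionary time accumulate
#' more change at every site, and subtracting the branch effect leaves
#' site-specific excesses. (An explicit division by branch time would
#' hand the correlation to a few high-leverage entries on near-zero
#' branches; the additive correction avoids that.) Each site's vector is
#' centred, and the Pearson correlation of two sites' centred profiles
#' across branches is the coevolution statistic. Per-branch synonymous
#' divergence (the time proxy) is reported alongside.
#'
#' @param codon_aln A [codon_alignment()].
#' @param tree Phylogeny (see [fitch_ancestors()]).
#' @param matrix Substitution matrix id/path/matrix (default BLOSUM62).
#' @param score `"binary"` change indicators (default) or `"blosum"`
#'   exchange-score magnitudes.
#' @return Object of class `coevolution_rates`: list with `R` (branches x
#'   sites centred rate matrix), `branches`, `t_branch` (synonymous
#'   divergence per branch), `n_changes` (inferred amino-acid changes per
#'   site), `taxa`.
#' @export
coevolution_rates <- function(codon_aln, tree, matrix = "BLOSUM62",
                              score = c("binary", "blosum")) {
  score <- match.arg(score)
  B <- substitution_matrix(matrix)
  fa <- fitch_ancestors(codon_aln, tree)
  gc <- genetic_code(codon_aln$genetic_code)
  brs <- fa$branches$branch
  L <- ncol(codon_aln$codons)
  U <- matrix(0, length(brs), L)
  syn <- numeric(length(brs))
  for (q in seq_along(brs)) {
    cmp <- branch_comparison(fa, brs[q], codon_aln$genetic_code,
                             mask_ambiguous = FALSE)
    pa <- unname(gc[cmp$parent_seq]); ch <- unname(gc[cmp$child_seq])
    chg <- which(cmp$usable & pa != ch)
    if (length(chg)) {
      if (identical(score, "blosum"))
        U[q, chg] <- sqrt(B[cbind(pa[chg], pa[chg])] + B[cbind(ch[chg], ch[chg])] -
                            2 * B[cbind(pa[chg], ch[chg])])
      else U[q, chg] <- 1
    }
    cnt <- branch_codon_counts(cmp, codon_aln$genetic_code)
    syn[q] <- sum(cnt$syn)
  }
  n_changes <- colSums(U > 0)
  t_branch <- (syn + 0.5) / L
  R <- U
  R <- R - rowMeans(R)
  R <- sweep(R, 2, colMeans(R))
  structure(list(R = R, branches = brs, t_branch = t_branch,
                 n_changes = n_changes, taxa = codon_aln$taxa,
                 fitch = fa),
            class = "coevolution_rates")
}

#' @export
print.coevolution_rates <- function(x, ...) {
  cat(sprintf("<coevolution_rates> %d branches x %d sites (%d with >= 3 changes)\n",
              nrow(x$R), ncol(x$R), sum(x$n_changes >= 3)))
  invisible(x)
}

# Observed correlations for all tested site pairs, given centred branch
# rate profiles. Tested sites need at least `min_changes` inferred
# amino-acid changes: correlated evolution is repeated co-substitution,
# and a site with one or two changes can coincide with another site by
# phylogenetic chance alone.
observed_correlations <- function(rates, min_changes = 3L) {
  sites <- which(rates$n_changes >= min_changes)
  if (length(sites) < 2)
    return(tibble(site_a = integer(), site_b = integer(), rho = numeric(),
                  stat = numeric()))
  D <- rates$R[, sites, drop = FALSE]
  Z <- scale(D)
  constant <- attr(Z, "scaled:scale") == 0
  Z[, constant] <- 0
  R <- crossprod(Z) / (nrow(D) - 1)
  # covariance carries the number of co-substitution branches: unlike the
  # correlation (capped at 1 by a single chance coincidence), repeated
  # coupling keeps increasing it, which is what the test must rank on
  CV <- crossprod(D) / (nrow(D) - 1)
  idx <- which(upper.tri(R), arr.ind = TRUE)
  out <- tibble(site_a = sites[idx[, 1]], site_b = sites[idx[, 2]],
                rho = R[idx], stat = CV[idx])
  out[order(out$site_a, out$site_b), ]
}

#' Permutation null distribution for the coevolution statistic
#'
#' Decouples site pairs while preserving each site's substitution
#' profile: in each replicate one random permutation of the branch index
#' is applied to one member of every tested site pair before
#' correlating, yielding a full family of null correlations between
#' sites with the observed per-site change counts but no shared
#' placement. The pooled draws (replicates x pairs) give raw p-values;
#' the per-replicate family maxima feed the step-down correction.
#' Replicates B = max(200, ceiling(n_perm / n_tested_pairs)), so at
#' least `n_perm` pooled draws are produced.
#'
#' @param rates A [coevolution_rates()] object.
#' @param n_perm Target number of pooled null draws (default 1e6;
#'   refuses below 100).
#' @param seed Integer seed.
#' @param min_changes Minimum inferred changes for a tested site.
#' @return Object of class `coevolution_null`: list with `null_stat`
#'   (B x n_pairs matrix of null covariances, columns ordered as the
#'   observed pair table), `pairs` (tibble site_a/site_b),
#'   `pooled_sorted` (sorted absolute pooled draws), `B`, `n_draws`,
#'   `seed`.
#' @export
permutation_null <- function(rates, n_perm = 1e6, seed = 1L,
                             min_changes = 3L) {
  if (n_perm < 100) abort("n_perm < 100 gives an uninformative null")
  stopifnot(inherits(rates, "coevolution_rates"))
  obs <- observed_correlations(rates, min_changes)
  if (!nrow(obs))
    abort("fewer than 2 tested sites", class = "compevo_degenerate_error")
  sites <- sort(unique(c(obs$site_a, obs$site_b)))
  J <- nrow(obs)
  B <- max(200L, as.integer(ceiling(n_perm / J)))
  m <- nrow(rates$R)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "permutation_null"))
  D <- rates$R[, sites, drop = FALSE]
  site_col <- stats::setNames(seq_along(sites), sites)
  ia <- site_col[as.character(obs$site_a)]
  ib <- site_col[as.character(obs$site_b)]
  null_stat <- matrix(NA_real_, B, J)
  for (b in seq_len(B)) {
    perm <- sample.int(m)
    # a permutation leaves column means intact: crossprod of the centred
    # columns is the exact covariance
    CV <- crossprod(D[perm, , drop = FALSE], D) / (m - 1)
    null_stat[b, ] <- CV[cbind(ia, ib)]
  }
  pooled <- sort(abs(null_stat[!is.na(null_stat)]))
  structure(list(null_stat = null_stat, pairs = obs[, c("site_a", "site_b")],
                 pooled_sorted = pooled, B = B, n_draws = length(pooled),
                 seed = seed),
            class = "coevolution_null")
}

#' @export
print.coevolution_null <- function(x, ...) {
  cat(sprintf("<coevolution_null> %d replicates x %d pairs (%d pooled draws)\n",
              x$B, ncol(x$null_stat), x$n_draws))
  invisible(x)
}

#' Step-down permutation adjustment (Westfall-Young maxT)
#'
#' Orders tested pairs by decreasing test statistic (the covariance of
#' the centred branch profiles; ties by site indices) and sets each
#' adjusted p-value to the fraction of null replicates whose maximum
#' statistic over the pair and all less-significant pairs reaches the
#' observed value; monotonicity is then enforced down the ordering, and
#' p_adj is never allowed below p_raw (computed from the pooled null
#' draws).
#'
#' @param observed Tibble with columns `site_a`, `site_b`, `rho`, `stat`
#'   (all tested pairs, as from the observed-correlation step).
#' @param null A [permutation_null()] result for the same pair family.
#' @return `observed` with added `p_raw`, `p_adj`, sorted by the
#'   step-down ordering.
#' @export
stepdown_adjust <- function(observed, null) {
  stopifnot(inherits(null, "coevolution_null"))
  if (!nrow(observed)) return(dplyr::mutate(observed, p_raw = numeric(0),
                                            p_adj = numeric(0)))
  if (is.null(observed$stat)) observed$stat <- observed$rho
  key_obs <- paste(observed$site_a, observed$site_b)
  key_null <- paste(null$pairs$site_a, null$pairs$site_b)
  colmap <- match(key_obs, key_null)
  if (anyNA(colmap)) abort("null was built for a different pair family")
  ord <- order(-abs(observed$stat), observed$site_a, observed$site_b)
  obs <- observed[ord, ]
  nr <- abs(null$null_stat[, colmap[ord], drop = FALSE])
  nr[is.na(nr)] <- 0
  J <- nrow(obs)
  # running max over the pair and all less-significant pairs, per replicate
  q <- nr
  if (J > 1) for (j in (J - 1):1) q[, j] <- pmax(q[, j], q[, j + 1])
  a_stat <- abs(obs$stat)
  tol <- 1e-12 * max(1, max(a_stat))
  p_adj <- vapply(seq_len(J), function(j) mean(q[, j] >= a_stat[j] - tol),
                  numeric(1))
  p_adj <- cummax(p_adj)
  n_pool <- length(null$pooled_sorted)
  p_raw <- (n_pool - findInterval(a_stat - tol, null$pooled_sorted)) / n_pool
  obs$p_raw <- p_raw
  obs$p_adj <- pmax(p_adj, p_raw)
  obs
}

#' Detect intramolecular coevolving site pairs
#'
#' Full pipeline: Fitch ancestral reconstruction, per-branch
#' divergence-corrected substitution-score rates, correlations over all
#' tested site pairs (sites with at least `min_changes` inferred
#' changes), permutation null, step-down adjustment, and
#' physico-chemical annotation. Pairs with adjusted p at or below
#' `alpha` are flagged significant.
#'
#' @param protein_aln A [protein_alignment()] (used for the property
#'   annotation; its columns index the reported sites).
#' @param codon_aln Matching [codon_alignment()].
#' @param tree Phylogeny relating the taxa (see [fitch_ancestors()]).
#' @param alpha Significance level on adjusted p-values (default 0.01).
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param n_perm Target pooled null draws (default 1e6).
#' @param seed Integer seed.
#' @param min_changes Minimum inferred amino-acid changes for a tested
#'   site (default 3: correlated evolution is repeated co-substitution;
#'   sites with fewer events only contribute phylogenetic coincidence).
#' @param scales Property scales for annotation
#'   (default [default_property_scales()]); `NULL` to skip.
#' @return Object of class `coevolution_result`: list with `pairs`
#'   (tibble: site_a, site_b, rho, p_raw, p_adj, significant, property
#'   correlation columns), `alpha`, `n_tested`, `null`, `rates`, `seed`.
#' @export
detect_coevolution <- function(protein_aln, codon_aln, tree, alpha = 0.01,
                               matrix = "BLOSUM62", n_perm = 1e6, seed = 1L,
                               min_changes = 3L,
                               scales = default_property_scales()) {
  rates <- coevolution_rates(codon_aln, tree, matrix)
  obs <- observed_correlations(rates, min_changes)
  if (nrow(obs) == 0) {
    pairs <- tibble(site_a = integer(), site_b = integer(), rho = numeric(),
                    p_raw = numeric(), p_adj = numeric(),
                    significant = logical())
    return(structure(list(pairs = pairs, alpha = alpha, n_tested = 0L,
                          null = NULL, rates = rates, seed = seed),
                     class = "coevolution_result"))
  }
  null <- permutation_null(rates, n_perm = n_perm, seed = seed,
                           min_changes = min_changes)
  pairs <- stepdown_adjust(obs, null)
  pairs$significant <- !is.na(pairs$p_adj) & pairs$p_adj <= alpha
  if (!is.null(scales)) pairs <- property_filter(pairs, protein_aln, scales)
  pairs <- pairs[order(pairs$p_adj, pairs$site_a, pairs$site_b), ]
  structure(list(pairs = pairs, alpha = alpha, n_tested = nrow(pairs),
                 null = null, rates = rates, seed = seed),
            class = "coevolution_result")
}

#' @export
print.coevolution_result <- function(x, ...) {
  cat(sprintf("<coevolution_result> %d pairs tested, %d significant at alpha = %g\n",
              x$n_tested, sum(x$pairs$significant), x$alpha))
  invisible(x)
}

#' @rdname detect_coevolution
#' @param x A `coevolution_result`.
#' @param ... Unused.
#' @export
tidy.coevolution_result <- function(x, ...) x$pairs

#' @export
glance.coevolution_result <- function(x, ...) {
  tibble(n_tested = x$n_tested, n_significant = sum(x$pairs$significant),
         alpha = x$alpha,
         null_replicates = if (!is.null(x$null)) x$null$B else NA_integer_,
         null_draws = if (!is.null(x$null)) x$null$n_draws else NA_integer_)
}

#' @export
autoplot.coevolution_result <- function(object, ...) {
  if (is.null(object$null)) abort("result holds no null distribution")
  nulldf <- tibble(abs_rho = object$null$pooled_sorted)
  ggplot2::ggplot(nulldf, ggplot2::aes(x = .data$abs_rho)) +
    ggplot2::geom_density(fill = "grey80", colour = NA) +
    ggplot2::geom_vline(data = object$pairs[object$pairs$significant, ],
                        ggplot2::aes(xintercept = abs(.data$rho)),
                        colour = "firebrick", linewidth = 0.3) +
    ggplot2::labs(x = "|rho|", y = "null density",
                  title = "Observed significant correlations vs permutation null") +
    ggplot2::theme_minimal()
}

#' Coevolution groups (maximal cliques of significant pairs)
#'
#' A group is a set of sites in which every pair shows significant
#' correlated evolution, i.e. a maximal clique of the significant-pair
#' graph; a site may belong to several groups.
#'
#' @param pairs Tibble with `site_a`, `site_b` (significant pairs only),
#'   or a `coevolution_result` (its significant pairs are used).
#' @return Tibble with `group_id`, `members` (list-column of sorted site
#'   indices), `size`; rows ordered lexicographically by members.
#' @export
build_groups <- function(pairs) {
  if (inherits(pairs, "coevolution_result"))
    pairs <- pairs$pairs[pairs$pairs$significant, ]
  if (!nrow(pairs))
    return(tibble(group_id = character(), members = list(), size = integer()))
  ed <- unique(t(apply(cbind(pairs$site_a, pairs$site_b), 1, sort)))
  g <- igraph::graph_from_edgelist(matrix(as.character(ed), ncol = 2),
                                   directed = FALSE)
  cl <- igraph::max_cliques(g, min = 2)
  members <- lapply(cl, function(v) sort(as.integer(names(v))))
  ord <- order(vapply(members, function(m)
    paste(sprintf("%06d", m), collapse = ""), character(1)))
  members <- members[ord]
  tibble(group_id = sprintf("G%d", seq_along(members)), members = members,
         size = lengths(members))
}

#' Physico-chemical property correlations for site pairs
#'
#' For each site pair and residue scale, correlates the per-sequence-pair
#' magnitudes of property change at the two sites. High values mean the
#' sites change their chemistry in step; used as an annotation filter on
#' coevolving pairs.
#'
#' @param pairs Tibble with `site_a`, `site_b`.
#' @param aln A [protein_alignment()].
#' @param scales Named list of residue scales
#'   (default [default_property_scales()]).
#' @param threshold Optional |correlation| threshold: if non-NULL, adds a
#'   logical `property_pass` column (any scale >= threshold).
#' @param min_pairs Minimum shared sequence pairs.
#' @return `pairs` with one `prop_<scale>` column per scale.
#' @export
property_filter <- function(pairs, aln, scales = default_property_scales(),
                            threshold = NULL, min_pairs = 6L) {
  stopifnot(is.list(scales), !is.null(names(scales)))
  sp <- seq_pairs(length(aln$taxa))
  deltas <- lapply(scales, function(sc) {
    miss <- setdiff(setdiff(unique(as.vector(aln$mat)), c("-", "X")), names(sc))
    if (length(miss)) abort(sprintf("scale lacks residues: %s",
                                    paste(miss, collapse = ", ")))
    v1 <- matrix(sc[aln$mat[sp[, 1], , drop = FALSE]], nrow = nrow(sp))
    v2 <- matrix(sc[aln$mat[sp[, 2], , drop = FALSE]], nrow = nrow(sp))
    abs(v1 - v2)  # NA where gap/X
  })
  for (nm in names(scales)) {
    dmat <- deltas[[nm]]
    pairs[[paste0("prop_", nm)]] <- vapply(seq_len(nrow(pairs)), function(q)
      cor_masked(dmat[, pairs$site_a[q]], dmat[, pairs$site_b[q]], min_pairs),
      numeric(1))
  }
  if (!is.null(threshold)) {
    pcols <- paste0("prop_", names(scales))
    pairs$property_pass <- apply(abs(as.matrix(pairs[, pcols])) >= threshold,
                                 1, any, na.rm = TRUE)
  }
  pairs
}

#' Write coevolving pairs / groups as TSV
#'
#' @param x A `coevolution_result` (pairs table) or [build_groups()]
#'   tibble.
#' @param path Output path.
#' @param map Optional [map_alignment_to_structure()] result to add
#'   reference-numbering columns.
#' @return `path`, invisibly.
#' @export
write_coevolution_tsv <- function(x, path, map = NULL) {
  if (inherits(x, "coevolution_result")) x <- x$pairs
  if ("members" %in% names(x)) {
    out <- data.frame(group_id = x$group_id,
                      members = vapply(x$members, paste, "", collapse = ","))
  } else {
    out <- as.data.frame(x)
    if (!is.null(map)) {
      out$ref_a <- map$map$ref_resno[match(out$site_a, map$map$column)]
      out$ref_b <- map$map$ref_resno[match(out$site_b, map$map$column)]
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
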