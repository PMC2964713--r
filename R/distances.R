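NT <- c("A", "C", "G", "T")
PURINE <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)

# Memoized per-code codon tables: codon strings, translation, per-position
# nucleotide index and degeneracy class (0/2/4-fold).
.codon_env <- new.env(parent = emptyenv())

codon_table <- function(code = "standard") {
  key <- as.character(code)
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  gc <- genetic_code(code)
  codons <- names(gc)
  pos_nt <- t(vapply(strsplit(codons, ""), match, integer(3), NT))
  deg <- matrix(0L, 64, 3, dimnames = list(codons, NULL))
  for (ci in seq_along(codons)) {
    cd <- strsplit(codons[ci], "")[[1]]
    for (p in 1:3) {
      nsyn <- 0L
      for (alt in setdiff(NT, cd[p])) {
        mut <- cd; mut[p] <- alt
        if (gc[paste(mut, collapse = "")] == gc[codons[ci]]) nsyn <- nsyn + 1L
      }
      deg[ci, p] <- if (nsyn == 3L) 4L else if (nsyn == 0L) 0L else 2L
    }
  }
  tab <- list(codons = codons, aa = unname(gc), pos_nt = pos_nt, deg = deg)
  .codon_env[[key]] <- tab
  tab
}

k2p_class <- function(ts, tv, L) {
  # Kimura two-parameter transition (A) and transversion (B) distances for
  # one degeneracy class; NA components are flagged saturated upstream.
  ts <- unname(ts); tv <- unname(tv); L <- unname(L)
  if (L <= 0) return(c(A = 0, B = 0, sat = 0))
  P <- ts / L; Q <- tv / L
  d1 <- 1 - 2 * P - Q; d2 <- 1 - 2 * Q
  if (d1 <= 0 || d2 <= 0) return(c(A = NA_real_, B = NA_real_, sat = 1))
  c(A = 0.5 * log(1 / d1) - 0.25 * log(1 / d2), B = 0.5 * log(1 / d2), sat = 0)
}

#' Li (1993) synonymous and nonsynonymous distances for a codon pair
#'
#' Classifies every codon position as 0-, 2- or 4-fold degenerate
#' (averaging the classes of the two codons), counts transitions and
#' transversions per class directly per position, applies the Kimura
#' two-parameter correction within each class, and combines classes with
#' the Li (1993) weighting:
#' `dS = (L2 A2 + L4 A4) / (L2 + L4) + B4` and
#' `dN = (L0 B0 + L2 B2) / (L0 + L2) + A0`.
#'
#' @param seq1,seq2 Codon vectors (3-letter strings; `---` = gap) or
#'   codon strings of equal length. Codon pairs with a gap or ambiguity in
#'   either sequence are skipped.
#' @param code Genetic code id.
#' @return List with `dS`, `dN`, `omega` (NA with `omega_flag = "inf"`
#'   when dS = 0 and dN > 0), `L` (sites per class), `ts`, `tv` (counts per
#'   class), `n_codons` (comparable codons), `saturated` (logical).
#' @examples
#' # one synonymous change at a fourfold site over 10 codons
#' li_ds_dn(strrep("GCT", 10), paste0(strrep("GCT", 9), "GCC"))$dS
#' @export
li_ds_dn <- function(seq1, seq2, code = "standard") {
  cnt <- codon_pair_counts(seq1, seq2, code)
  li_from_counts(colSums(cnt$L), colSums(cnt$ts), colSums(cnt$tv),
                 n_codons = cnt$n_codons)
}

# Per-codon degeneracy-class site and difference counts for a pair of
# codon sequences; rows = comparable codons (others dropped), columns =
# class 0/2/4 for sites (L), transitions (ts) and transversions (tv).
codon_pair_counts <- function(seq1, seq2, code = "standard") {
  s1 <- split_codons(seq1); s2 <- split_codons(seq2)
  if (length(s1) != length(s2))
    abort("sequences differ in codon length", class = "compevo_length_error")
  tab <- codon_table(code)
  i1 <- match(s1, tab$codons); i2 <- match(s2, tab$codons)
  ok <- !is.na(i1) & !is.na(i2) & tab$aa[i1] != "*" & tab$aa[i2] != "*"
  if (!any(ok)) abort("no comparable codons", class = "compevo_degenerate_error")
  i1 <- i1[ok]; i2 <- i2[ok]
  n <- length(i1)
  L <- ts <- tv <- matrix(0, n, 3, dimnames = list(NULL, c("0", "2", "4")))
  for (p in 1:3) {
    d1 <- as.character(tab$deg[i1, p]); d2 <- as.character(tab$deg[i2, p])
    for (k in c("0", "2", "4"))
      L[, k] <- L[, k] + 0.5 * ((d1 == k) + (d2 == k))
    n1 <- tab$pos_nt[i1, p]; n2 <- tab$pos_nt[i2, p]
    diff <- n1 != n2
    if (any(diff)) {
      is_ts <- diff & PURINE[NT[n1]] == PURINE[NT[n2]]
      is_tv <- diff & !is_ts
      for (k in c("0", "2", "4")) {
        ts[, k] <- ts[, k] + 0.5 * (is_ts * ((d1 == k) + (d2 == k)))
        tv[, k] <- tv[, k] + 0.5 * (is_tv * ((d1 == k) + (d2 == k)))
      }
    }
  }
  list(L = L, ts = ts, tv = tv, which = which(ok), n_codons = n)
}

# Combine class counts into Li (1993) dS/dN.
li_from_counts <- function(L, ts, tv, n_codons) {
  L <- unname(L); ts <- unname(ts); tv <- unname(tv)
  k0 <- k2p_class(ts[1], tv[1], L[1])
  k2 <- k2p_class(ts[2], tv[2], L[2])
  k4 <- k2p_class(ts[3], tv[3], L[3])
  saturated <- any(c(k0["sat"], k2["sat"], k4["sat"]) == 1)
  dS <- dN <- NA_real_
  if (!saturated) {
    dS <- (L[2] * k2[["A"]] + L[3] * k4[["A"]]) / (L[2] + L[3]) + k4[["B"]]
    dN <- (L[1] * k0[["B"]] + L[2] * k2[["B"]]) / (L[1] + L[2]) + k0[["A"]]
  }
  omega <- NA_real_; omega_flag <- NA_character_
  if (!saturated) {
    if (dS > 0) omega <- dN / dS
    else if (dN > 0) omega_flag <- "inf"
    else omega <- 0
  } else omega_flag <- "saturated"
  L_out <- setNames(L, c("0", "2", "4"))
  list(dS = unname(dS), dN = unname(dN), omega = unname(omega),
       omega_flag = omega_flag, L = L_out,
       ts = setNames(ts, c("0", "2", "4")), tv = setNames(tv, c("0", "2", "4")),
       n_codons = n_codons, saturated = saturated)
}

split_codons <- function(x) {
  if (length(x) == 1 && nchar(x) > 3) {
    s <- toupper(x)
    if (nchar(s) %% 3 != 0) abort("sequence length not a multiple of 3",
                                  class = "compevo_length_error")
    substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
  } else toupper(x)
}

#' Pairwise synonymous divergence matrix
#'
#' Li (1993) dS for every sequence pair of a codon alignment, used as the
#' proxy for divergence time in the coevolution statistic. Values below
#' `epsilon` are floored to `epsilon` (identical pairs would otherwise
#' divide by zero); saturated pairs are set to `cap`. Both are flagged.
#'
#' @param codon_aln A [codon_alignment()].
#' @param epsilon Divergence floor (substitutions/site), default 1e-4.
#' @param cap Value assigned to saturated pairs, default 5.
#' @return Object of class `pair_divergence`: list with symmetric matrix
#'   `t` (taxa x taxa), `flags` tibble (taxon_1, taxon_2, flag) and the
#'   parameters.
#' @export
pairwise_synonymous_distance <- function(codon_aln, epsilon = 1e-4, cap = 5) {
  taxa <- codon_aln$taxa
  n <- length(taxa)
  t_kl <- matrix(0, n, n, dimnames = list(taxa, taxa))
  flags <- list()
  for (k in seq_len(n - 1)) for (l in (k + 1):n) {
    res <- tryCatch(li_ds_dn(codon_aln$codons[k, ], codon_aln$codons[l, ],
                             code = codon_aln$genetic_code),
                    compevo_degenerate_error = function(e) NULL)
    if (is.null(res) || res$saturated) {
      val <- cap
      flags[[length(flags) + 1]] <- tibble(taxon_1 = taxa[k], taxon_2 = taxa[l],
                                           flag = "saturated")
    } else if (res$dS < epsilon) {
      val <- epsilon
      flags[[length(flags) + 1]] <- tibble(taxon_1 = taxa[k], taxon_2 = taxa[l],
                                           flag = "floored")
    } else val <- res$dS
    t_kl[k, l] <- t_kl[l, k] <- val
  }
  structure(list(t = t_kl, flags = dplyr::bind_rows(flags),
                 epsilon = epsilon, cap = cap),
            class = "pair_divergence")
}

#' @export
print.pair_divergence <- function(x, ...) {
  cat(sprintf("<pair_divergence> %d taxa, %d flagged pairs (floor %g, cap %g)\n",
              nrow(x$t), nrow(x$flags) %||% 0, x$epsilon, x$cap))
  invisible(x)
}
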