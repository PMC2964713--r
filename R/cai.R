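#' Codon usage reference (relative adaptiveness)
#'
#' Builds the per-codon relative adaptiveness table `w` used by the codon
#' adaptation index. Input may be raw codon counts/frequencies or already
#' normalised weights; each synonymous family is rescaled so its most used
#' codon has `w = 1`. Stop codons are removed.
#'
#' @param x Named numeric vector (names = codons) of counts, frequencies
#'   or weights, or a two-column data frame (codon, value).
#' @param code Genetic code id.
#' @return Object of class `codon_usage_reference`: tibble with columns
#'   `codon`, `aa`, `w`.
#' @export
codon_usage_reference <- function(x, code = "standard") {
  if (is.data.frame(x)) x <- setNames(as.numeric(x[[2]]), toupper(x[[1]]))
  names(x) <- gsub("U", "T", toupper(names(x)))
  gc <- genetic_code(code)
  bad <- setdiff(names(x), names(gc))
  if (length(bad)) abort(sprintf("unknown codons: %s", paste(bad, collapse = ", ")))
  if (any(x < 0)) abort("codon usage values must be non-negative")
  df <- tibble(codon = names(x), value = unname(x), aa = unname(gc[names(x)]))
  df <- df[df$aa != "*", ]
  df <- dplyr::group_by(df, .data$aa)
  df <- dplyr::mutate(df, w = .data$value / max(.data$value))
  df <- dplyr::ungroup(df)
  if (!all(is.finite(df$w))) abort("a synonymous family has all-zero usage")
  structure(df[, c("codon", "aa", "w")], class = c("codon_usage_reference",
                                                   class(df)))
}

#' Read a codon usage reference from a two-column text table
#'
#' @param path Whitespace- or tab-separated file with columns codon and
#'   weight (or raw count); lines starting with `#` are ignored.
#' @param code Genetic code id.
#' @return A [codon_usage_reference()].
#' @export
read_codon_usage <- function(path, code = "standard") {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("codon", "value"),
                   colClasses = c("character", "numeric"))
  codon_usage_reference(df, code = code)
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness `w` over the codons of a
#' coding sequence. Single-codon families (Met, Trp) and stop codons are
#' excluded from the product, following the standard CAI definition.
#'
#' @param cds Coding DNA sequence (length multiple of 3, no internal stop).
#' @param ref A [codon_usage_reference()].
#' @param missing_codon `"error"` (default) to fail when a scored codon is
#'   absent from the reference, or a numeric pseudo-weight floor in (0, 1]
#'   to use instead.
#' @return CAI value in (0, 1].
#' @examples
#' ref <- codon_usage_reference(c(AAA = 100, AAG = 25, ATG = 100))
#' cai("ATGAAA", ref)        # only optimal codons: 1
#' cai("ATGAAGAAA", ref)     # sqrt(0.25 * 1) = 0.5
#' @export
cai <- function(cds, ref, missing_codon = "error") {
  s <- gsub("U", "T", toupper(cds))
  if (nchar(s) %% 3 != 0)
    abort("CDS length is not a multiple of 3", class = "compevo_length_error")
  codons <- substring(s, seq(1, nchar(s) - 2, by = 3), seq(3, nchar(s), by = 3))
  gc <- genetic_code()
  aa <- unname(gc[codons])
  if (anyNA(aa)) abort(sprintf("untranslatable codon: %s",
                               codons[which(is.na(aa))[1]]))
  if (any(aa[-length(aa)] == "*"))
    abort("internal stop codon", class = "compevo_translation_error")
  fam_sizes <- table(unname(gc[gc != "*"]))
  scorable <- aa != "*" & fam_sizes[aa] > 1
  codons <- codons[scorable]
  if (!length(codons))
    abort("no scorable codons (only single-codon families/stops)",
          class = "compevo_degenerate_error")
  w <- ref$w[match(codons, ref$codon)]
  if (anyNA(w)) {
    if (identical(missing_codon, "error"))
      abort(sprintf("codon %s absent from reference", codons[which(is.na(w))[1]]))
    w[is.na(w)] <- as.numeric(missing_codon)
  }
  exp(mean(log(w)))
}
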