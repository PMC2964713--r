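AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")
AA_ALLOWED <- c(AA_ALPHABET, "X", "-")

#' Genetic code table
#'
#' Returns a named character vector mapping codons (DNA, upper case) to
#' one-letter amino acids, with `*` for stop codons.
#'
#' @param id Genetic code identifier as in [Biostrings::getGeneticCode()]
#'   (`"1"` or `"standard"` for the standard code).
#' @return Named character vector of length 64.
#' @export
genetic_code <- function(id = "standard") {
  if (identical(tolower(id), "standard")) id <- "1"
  Biostrings::getGeneticCode(id)
}

#' Protein alignment container
#'
#' Builds a validated protein multiple sequence alignment from named,
#' equal-length, aligned sequences. Residues must be the 20 amino-acid
#' one-letter codes, `X` (unknown) or `-` (gap).
#'
#' @param seqs Named character vector of aligned sequences, or a character
#'   matrix (rows = taxa, one residue per cell) with rownames.
#' @return An object of class `protein_alignment` with fields `taxa`,
#'   `mat` (taxa x columns character matrix) and `length`.
#' @examples
#' aln <- protein_alignment(c(s1 = "MKL", s2 = "MRL", s3 = "MKI", s4 = "MRI"))
#' aln$length
#' @export
protein_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- seqs
    taxa <- rownames(mat)
  } else {
    taxa <- names(seqs)
    if (is.null(taxa)) abort("sequences must be named", class = "compevo_id_error")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      abort(sprintf("ragged alignment: lengths %s", paste(unique(lens), collapse = ", ")),
            class = "compevo_format_error")
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- taxa
  }
  if (anyDuplicated(taxa)) {
    abort(sprintf("duplicate sequence identifiers: %s",
                  paste(unique(taxa[duplicated(taxa)]), collapse = ", ")),
          class = "compevo_id_error")
  }
  bad <- setdiff(unique(as.vector(mat)), AA_ALLOWED)
  if (length(bad)) {
    abort(sprintf("invalid residue symbols: %s", paste(bad, collapse = ", ")),
          class = "compevo_format_error")
  }
  if (nrow(mat) < 4) {
    warn("fewer than 4 sequences: pairwise site statistics will be weak")
  }
  structure(list(taxa = taxa, mat = mat, length = ncol(mat)),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %d taxa x %d columns\n",
              length(x$taxa), x$length))
  invisible(x)
}

#' @export
as.character.protein_alignment <- function(x, ...) {
  setNames(apply(x$mat, 1, paste, collapse = ""), x$taxa)
}

#' Codon alignment container
#'
#' @param codons Character matrix of 3-letter codons (or `"---"` gap
#'   triplets), rows named by taxon.
#' @param code Genetic code id (see [genetic_code()]).
#' @return Object of class `codon_alignment` with fields `taxa`, `codons`,
#'   `genetic_code`.
#' @export
codon_alignment <- function(codons, code = "standard") {
  taxa <- rownames(codons)
  if (is.null(taxa) || anyDuplicated(taxa))
    abort("codon matrix must have unique rownames", class = "compevo_id_error")
  if (any(nchar(codons) != 3))
    abort("all entries must be 3-letter codons or '---'", class = "compevo_format_error")
  gc <- genetic_code(code)
  nongap <- codons[codons != "---"]
  aas <- gc[nongap]
  if (anyNA(aas))
    abort(sprintf("untranslatable codons: %s",
                  paste(unique(nongap[is.na(aas)]), collapse = ", ")),
          class = "compevo_format_error")
  if (any(aas == "*"))
    abort("internal stop codon in alignment", class = "compevo_translation_error")
  structure(list(taxa = taxa, codons = codons, genetic_code = code),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d taxa x %d codons (code: %s)\n",
              length(x$taxa), ncol(x$codons), x$genetic_code))
  invisible(x)
}

#' Translate a codon alignment back to its protein alignment
#'
#' Gap triplets become gap residues; this is the inverse of
#' [backtranslate()] on gap placement.
#'
#' @param codon_aln A `codon_alignment`.
#' @return A `protein_alignment`.
#' @export
translate_alignment <- function(codon_aln) {
  gc <- genetic_code(codon_aln$genetic_code)
  mat <- codon_aln$codons
  aa <- matrix("-", nrow(mat), ncol(mat), dimnames = dimnames(mat))
  nz <- mat != "---"
  aa[nz] <- unname(gc[mat[nz]])
  protein_alignment(aa)
}

#' Read an aligned or unaligned FASTA file
#'
#' @param path FASTA file path.
#' @param kind `"protein"` returns a validated [protein_alignment()];
#'   `"nucleotide"` returns a named character vector of raw sequences
#'   (no length validation, suitable for unaligned CDS).
#' @return A `protein_alignment` or a named character vector.
#' @export
read_alignment <- function(path, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (kind == "protein") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- setNames(as.character(ss), names(ss))
    # readBStringSet tolerates ragged records; alignment validation is ours
    protein_alignment(seqs)
  } else {
    ss <- Biostrings::readDNAStringSet(path)
    if (anyDuplicated(names(ss)))
      abort("duplicate sequence identifiers", class = "compevo_id_error")
    setNames(as.character(ss), names(ss))
  }
}

#' Write sequences to FASTA (wrapped at 80 columns)
#'
#' @param x Named character vector, `protein_alignment`, or
#'   `codon_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "protein_alignment")) x <- as.character(x)
  if (inherits(x, "codon_alignment"))
    x <- setNames(apply(x$codons, 1, paste, collapse = ""), x$taxa)
  ss <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Back-translate a protein alignment onto unaligned coding sequences
#'
#' Threads each taxon's coding sequence through its aligned protein row:
#' gap columns become `---` triplets, residue columns receive consecutive
#' codons. Every codon is checked to translate to the aligned residue.
#'
#' @param protein_aln A [protein_alignment()].
#' @param cds Named character vector of unaligned coding sequences (DNA),
#'   one per taxon in `protein_aln`. A trailing stop codon is allowed and
#'   dropped.
#' @param code Genetic code id.
#' @return A [codon_alignment()].
#' @examples
#' aln <- protein_alignment(c(a = "M-K", b = "MLK", c = "M-K", d = "MLK"))
#' cds <- c(a = "ATGAAA", b = "ATGCTGAAG", c = "ATGAAG", d = "ATGTTAAAA")
#' backtranslate(aln, cds)
#' @export
backtranslate <- function(protein_aln, cds, code = "standard") {
  gc <- genetic_code(code)
  missing_taxa <- setdiff(protein_aln$taxa, names(cds))
  if (length(missing_taxa))
    abort(sprintf("no coding sequence for: %s", paste(missing_taxa, collapse = ", ")),
          class = "compevo_id_error")
  out <- matrix("---", length(protein_aln$taxa), protein_aln$length,
                dimnames = list(protein_aln$taxa, NULL))
  for (tx in protein_aln$taxa) {
    row <- protein_aln$mat[tx, ]
    s <- toupper(gsub("U", "T", cds[[tx]]))
    ngap <- which(row != "-")
    codons <- substring(s, seq(1, nchar(s) - 2, by = 3), seq(3, nchar(s), by = 3))
    # tolerate one trailing stop codon on the CDS
    if (length(codons) == length(ngap) + 1 &&
        !is.na(gc[codons[length(codons)]]) && gc[codons[length(codons)]] == "*") {
      codons <- codons[-length(codons)]
    }
    if (nchar(s) %% 3 != 0 || length(codons) != length(ngap))
      abort(sprintf("taxon %s: CDS length %d does not match %d aligned residues",
                    tx, nchar(s), length(ngap)),
            class = "compevo_length_error")
    aa <- unname(gc[codons])
    mism <- which(aa != row[ngap] & row[ngap] != "X")
    if (length(mism))
      abort(sprintf("taxon %s: codon %s translates to %s but alignment has %s at column %d",
                    tx, codons[mism[1]], aa[mism[1]], row[ngap][mism[1]], ngap[mism[1]]),
            class = "compevo_translation_error")
    out[tx, ngap] <- codons
  }
  codon_alignment(out, code = code)
}
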