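#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard NCBI scoring-matrix layout (comment lines starting
#' with `#`, a header row of residue symbols, then one labelled row per
#' residue). The package bundles BLOSUM62 in this format.
#'
#' @param path Matrix file; default the bundled BLOSUM62.
#' @return Square numeric matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "BLOSUM62.txt", package = "compevo")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labs <- vapply(rows, `[`, "", 1)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  dimnames(vals) <- list(labs, header)
  if (!identical(rownames(vals), colnames(vals)))
    abort("matrix rows and columns disagree", class = "compevo_format_error")
  vals
}

#' Fetch a substitution matrix by id
#'
#' `"BLOSUM62"` resolves to the bundled NCBI-format file; a file path is
#' read directly.
#'
#' @param matrix Matrix id or path.
#' @return Numeric score matrix.
#' @export
substitution_matrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) return(matrix)
  if (identical(toupper(matrix), "BLOSUM62")) return(read_substitution_matrix())
  if (file.exists(matrix)) return(read_substitution_matrix(matrix))
  abort(sprintf("unknown substitution matrix: %s", matrix))
}
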