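ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305)

#' Parse a PDB structure into a residue/atom model
#'
#' Reads ATOM records via bio3d, keeping heavy atoms only: HETATM
#' (including waters), hydrogens/deuteriums and all but the first altloc
#' are dropped. Insertion codes are preserved in residue keys.
#'
#' @param path PDB file.
#' @param chain Optional chain selector (single chain id); default all.
#' @return Object of class `structure_model`: list with `atoms` tibble
#'   (chain, resno, icode, resid, elety, element, mass, x, y, z,
#'   res_key), `residues` tibble (res_key, chain, resno, icode, resid,
#'   aa, n_atoms, in model order) and `source`.
#' @export
parse_structure <- function(path, chain = NULL) {
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) abort(sprintf("cannot parse PDB %s: %s",
                                                    path, conditionMessage(e)),
                                            class = "compevo_format_error"))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) abort("no ATOM records", class = "compevo_format_error")
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) abort(sprintf("no ATOM records for chain %s", chain),
                       class = "compevo_format_error")
  at <- at[!at$resid %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  elem <- toupper(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                         substr(gsub("[0-9'\"]", "", at$elety), 1, 1),
                         trimws(at$elesy)))
  at <- at[!elem %in% c("H", "D"), , drop = FALSE]
  elem <- elem[!elem %in% c("H", "D")]
  icode <- ifelse(is.na(at$insert), "", at$insert)
  res_key <- paste0(at$chain, ":", at$resno, icode)
  # first altloc instance of each atom kept
  keep <- !duplicated(paste(res_key, at$elety))
  dup_extra <- any(!keep & (is.na(at$alt) | at$alt %in% c("", "A")) &
                     !nzchar(ifelse(is.na(at$alt), "", at$alt)))
  if (dup_extra) warn("duplicate atoms within a residue: first kept")
  at <- at[keep, , drop = FALSE]; elem <- elem[keep]
  res_key <- res_key[keep]; icode <- icode[keep]
  mass <- unname(ATOMIC_MASS[elem])
  if (anyNA(mass)) {
    warn(sprintf("unknown elements (%s): mass 12 assumed",
                 paste(unique(elem[is.na(mass)]), collapse = ",")))
    mass[is.na(mass)] <- 12
  }
  atoms <- tibble(chain = at$chain, resno = at$resno, icode = icode,
                  resid = at$resid, elety = at$elety, element = elem,
                  mass = mass, x = at$x, y = at$y, z = at$z,
                  res_key = res_key)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    abort("non-finite coordinates", class = "compevo_format_error")
  first <- !duplicated(atoms$res_key)
  residues <- tibble(res_key = atoms$res_key[first], chain = atoms$chain[first],
                     resno = atoms$resno[first], icode = atoms$icode[first],
                     resid = atoms$resid[first],
                     aa = suppressWarnings(bio3d::aa321(atoms$resid[first])),
                     n_atoms = as.integer(table(atoms$res_key)[atoms$res_key[first]]))
  structure(list(atoms = atoms, residues = residues, source = path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d residues, %d heavy atoms (%s)\n",
              nrow(x$residues), nrow(x$atoms), x$source))
  invisible(x)
}

#' Extract one residue's atom coordinates
#'
#' @param model A [parse_structure()] model.
#' @param res Residue key (`chain:resno[icode]`) or positional index.
#' @return Numeric matrix (atoms x 3) with a `mass` attribute.
#' @export
residue_atoms <- function(model, res) {
  key <- if (is.numeric(res)) model$residues$res_key[res] else res
  a <- model$atoms[model$atoms$res_key == key, , drop = FALSE]
  if (!nrow(a)) abort(sprintf("no atoms for residue %s", key))
  m <- as.matrix(a[, c("x", "y", "z")])
  attr(m, "mass") <- a$mass
  m
}

as_coords <- function(x) {
  if (is.matrix(x)) return(x)
  as.matrix(as.data.frame(x)[, c("x", "y", "z")])
}

#' Mean inter-atomic distance between two residues
#'
#' The average over all N x K heavy-atom pairs of the Euclidean distance:
#' `d = (1/(N K)) sum_i sum_j ||a_i - b_j||`.
#'
#' @param res_a,res_b Atom coordinate matrices (atoms x 3) or objects
#'   accepted by [residue_atoms()].
#' @return Distance in Angstrom.
#' @examples
#' mean_residue_distance(rbind(c(0, 0, 0)), rbind(c(3, 4, 0)))  # 5
#' @export
mean_residue_distance <- function(res_a, res_b) {
  A <- as_coords(res_a); B <- as_coords(res_b)
  if (!nrow(A) || !nrow(B)) abort("empty residue", class = "compevo_degenerate_error")
  mean(sqrt(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)))
}

#' Minimum inter-atomic distance and contact test
#'
#' @param res_a,res_b Atom coordinate matrices (atoms x 3).
#' @return `min_atom_distance`: the smallest atom-atom distance in
#'   Angstrom.
#' @export
min_atom_distance <- function(res_a, res_b) {
  A <- as_coords(res_a); B <- as_coords(res_b)
  if (!nrow(A) || !nrow(B)) abort("empty residue", class = "compevo_degenerate_error")
  min(sqrt(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)))
}

#' @rdname min_atom_distance
#' @param cutoff Contact cutoff in Angstrom, inclusive (default 4.0).
#' @return `contact`: TRUE when the closest atoms are at or below
#'   `cutoff`.
#' @export
contact <- function(res_a, res_b, cutoff = 4.0) {
  min_atom_distance(res_a, res_b) <= cutoff
}

#' All-pairs residue contact map
#'
#' @param model A [parse_structure()] model.
#' @param cutoff Contact cutoff (Angstrom, inclusive; default 4.0).
#' @return Object of class `contact_map`: list with `pairs` tibble
#'   (res_i, res_j keys with i < j in model order, mean_dist, min_dist,
#'   contact), `residues`, `cutoff`.
#' @export
contact_map <- function(model, cutoff = 4.0) {
  keys <- model$residues$res_key
  n <- length(keys)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  ridx <- match(model$atoms$res_key, keys)
  sq <- rowSums(xyz^2)
  dall <- sqrt(pmax(outer(sq, sq, `+`) - 2 * xyz %*% t(xyz), 0))
  alist <- split(seq_len(nrow(xyz)), ridx)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  md <- mn <- numeric(nrow(idx))
  for (q in seq_len(nrow(idx))) {
    blk <- dall[alist[[idx[q, 1]]], alist[[idx[q, 2]]], drop = FALSE]
    md[q] <- mean(blk); mn[q] <- min(blk)
  }
  structure(list(pairs = tibble(res_i = keys[idx[, 1]], res_j = keys[idx[, 2]],
                                mean_dist = md, min_dist = mn,
                                contact = mn <= cutoff),
                 residues = model$residues, cutoff = cutoff),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d residues, %d contacts at <= %g A\n",
              nrow(x$residues), sum(x$pairs$contact), x$cutoff))
  invisible(x)
}

#' @export
tidy.contact_map <- function(x, ...) x$pairs

#' @export
autoplot.contact_map <- function(object, ...) {
  keys <- object$residues$res_key
  df <- object$pairs
  df$i <- match(df$res_i, keys); df$j <- match(df$res_j, keys)
  both <- rbind(df[, c("i", "j", "min_dist", "contact")],
                setNames(df[, c("j", "i", "min_dist", "contact")],
                         c("i", "j", "min_dist", "contact")))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$i, y = .data$j,
                                     fill = .data$min_dist)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = both[both$contact, ], size = 0.3,
                        colour = "firebrick") +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "residue", y = "residue", fill = "min dist (A)") +
    ggplot2::theme_minimal()
}

# Min-atom distance lookup on a contact map (symmetric in arguments).
cm_min_dist <- function(cm, key_a, key_b) {
  if (key_a == key_b) return(0)
  hit <- (cm$pairs$res_i == key_a & cm$pairs$res_j == key_b) |
    (cm$pairs$res_i == key_b & cm$pairs$res_j == key_a)
  if (!any(hit)) abort(sprintf("pair %s / %s not in contact map", key_a, key_b))
  cm$pairs$min_dist[which(hit)[1]]
}

residue_centres <- function(model, weighted = TRUE) {
  keys <- model$residues$res_key
  t(vapply(keys, function(k) {
    m <- residue_atoms(model, k)
    w <- if (weighted) attr(m, "mass") else rep(1, nrow(m))
    colSums(m * w) / sum(w)
  }, numeric(3)))
}

kabsch <- function(P, Q) {
  # optimal rotation R with P %*% R ~ Q (both centred)
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Residue mass-centre RMSD between two structures
#'
#' Computes mass-weighted centres for each residue and the RMSD over
#' paired centres, optionally after optimal rigid (Kabsch) superposition.
#' Comparing homology models in arbitrary frames requires superposition;
#' it can be disabled to measure displacement in a shared frame.
#'
#' @param s1,s2 [parse_structure()] models.
#' @param pairing Two-column matrix/data.frame of residue indices (or
#'   keys) pairing s1 to s2; default pairs residues in model order
#'   (requires equal residue counts).
#' @param superpose Apply Kabsch superposition first (default TRUE;
#'   requires >= 3 pairs).
#' @param weighted Mass-weighted centres (default) or geometric centres.
#' @return RMSD in Angstrom.
#' @export
mass_center_rmsd <- function(s1, s2, pairing = NULL, superpose = TRUE,
                             weighted = TRUE) {
  c1 <- residue_centres(s1, weighted)
  c2 <- residue_centres(s2, weighted)
  if (is.null(pairing)) {
    if (nrow(c1) != nrow(c2))
      abort("unequal residue counts: supply an explicit pairing",
            class = "compevo_pairing_error")
    P <- c1; Q <- c2
  } else {
    pairing <- as.matrix(pairing)
    if (ncol(pairing) != 2) abort("pairing must have two columns",
                                  class = "compevo_pairing_error")
    i1 <- if (is.numeric(pairing)) as.integer(pairing[, 1]) else
      match(pairing[, 1], s1$residues$res_key)
    i2 <- if (is.numeric(pairing)) as.integer(pairing[, 2]) else
      match(pairing[, 2], s2$residues$res_key)
    if (anyNA(i1) || anyNA(i2) || any(i1 < 1 | i1 > nrow(c1)) ||
        any(i2 < 1 | i2 > nrow(c2)))
      abort("pairing refers to missing residues", class = "compevo_pairing_error")
    P <- c1[i1, , drop = FALSE]; Q <- c2[i2, , drop = FALSE]
  }
  if (superpose) {
    if (nrow(P) < 3) abort("superposition needs >= 3 paired residues",
                           class = "compevo_degenerate_error")
    mp <- colMeans(P); mq <- colMeans(Q)
    Pc <- sweep(P, 2, mp); Qc <- sweep(Q, 2, mq)
    R <- kabsch(Pc, Qc)
    P <- Pc %*% R; Q <- Qc
  }
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Map alignment columns to reference-structure residue numbers
#'
#' Aligns the reference taxon's ungapped sequence to the structure's
#' residue sequence (Needleman-Wunsch via Biostrings when lengths differ,
#' e.g. residues missing from density) and assigns each alignment column
#' where the reference has a residue to a structure residue number. All
#' downstream site labels use this numbering.
#'
#' @param aln A [protein_alignment()].
#' @param ref_taxon Name of the reference row.
#' @param model A [parse_structure()] model.
#' @return Object of class `alignment_structure_map`: list with `map`
#'   tibble (column, ref_resno, res_key, aa_alignment, aa_structure,
#'   matched; NA ref_resno = unmapped), `ref_taxon`, `source`.
#' @export
map_alignment_to_structure <- function(aln, ref_taxon, model) {
  if (!ref_taxon %in% aln$taxa)
    abort(sprintf("reference taxon %s absent", ref_taxon),
          class = "compevo_id_error")
  row <- aln$mat[ref_taxon, ]
  cols <- which(row != "-")
  refseq <- row[cols]
  strseq <- model$residues$aa
  n_ref <- length(refseq); n_str <- length(strseq)
  if (n_ref == n_str) {
    ref_pos <- seq_len(n_ref); str_pos <- seq_len(n_str)
  } else {
    pa <- Biostrings::pairwiseAlignment(paste(refseq, collapse = ""),
                                        paste(strseq, collapse = ""),
                                        type = "global",
                                        substitutionMatrix = substitution_matrix("BLOSUM62")[
                                          c(AA_ALPHABET, "X"), c(AA_ALPHABET, "X")],
                                        gapOpening = 10, gapExtension = 2)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ip <- cumsum(p != "-"); is_ <- cumsum(s != "-")
    keep <- p != "-" & s != "-"
    ref_pos <- ip[keep]; str_pos <- is_[keep]
  }
  matched <- refseq[ref_pos] == strseq[str_pos]
  if (sum(matched) < 0.5 * n_ref)
    abort("fewer than 50% of reference residues matched the structure",
          class = "compevo_mapping_error")
  if (any(!matched))
    warn(sprintf("%d residue-name mismatches in structure mapping retained",
                 sum(!matched)))
  map <- tibble(column = cols[ref_pos],
                ref_resno = model$residues$resno[str_pos],
                res_key = model$residues$res_key[str_pos],
                aa_alignment = refseq[ref_pos],
                aa_structure = strseq[str_pos],
                matched = matched)
  unmapped <- setdiff(seq_len(aln$length), map$column)
  if (length(unmapped))
    map <- rbind(map, tibble(column = unmapped, ref_resno = NA_integer_,
                             res_key = NA_character_, aa_alignment = row[unmapped],
                             aa_structure = NA_character_, matched = NA))
  map <- map[order(map$column), ]
  structure(list(map = map, ref_taxon = ref_taxon, source = model$source),
            class = "alignment_structure_map")
}

#' @export
print.alignment_structure_map <- function(x, ...) {
  cat(sprintf("<alignment_structure_map> %d/%d columns mapped (reference %s)\n",
              sum(!is.na(x$map$ref_resno)), nrow(x$map), x$ref_taxon))
  invisible(x)
}

#' @export
tidy.alignment_structure_map <- function(x, ...) x$map

# "D41"-style label for an alignment column under a structure map.
site_label <- function(map, column) {
  r <- map$map[map$map$column == column, ]
  if (!nrow(r) || is.na(r$ref_resno[1])) return(sprintf("col%d", column))
  paste0(r$aa_structure[1], r$ref_resno[1])
}
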