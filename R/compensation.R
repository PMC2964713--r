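#' Functional region annotation for angiogenin (hAng/1ANG numbering)
#'
#' Default regions: catalytic triad His13/Lys40/His114, B1 binding
#' subsite (Thr44, Ser118), B2 subsite (108), P2 subsite (5, 8), nuclear
#' localization signal Arg31-Leu35, and the putative cell-binding region
#' (59-68, 108-110, 119).
#'
#' @param regions Optional named list of integer residue vectors to
#'   replace the defaults.
#' @return Named list of reference residue numbers, class
#'   `functional_annotation`.
#' @export
functional_regions <- function(regions = NULL) {
  regions <- regions %||% list(
    active_site = c(13L, 40L, 114L),
    B1 = c(44L, 118L),
    B2 = 108L,
    P2 = c(5L, 8L),
    NLS = 31:35,
    putative_binding = c(59:68, 108:110, 119L))
  if (is.null(names(regions)) || anyDuplicated(names(regions)))
    abort("regions must have unique names")
  if (any(unlist(regions) < 1)) abort("residue numbers must be positive")
  structure(lapply(regions, as.integer), class = "functional_annotation")
}

#' Read/write a functional-region config (JSON)
#'
#' @param path JSON file: object of region name to residue-number array.
#' @return A [functional_regions()] annotation.
#' @export
read_regions <- function(path) {
  functional_regions(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_regions
#' @param regions Annotation (named list of residue numbers).
#' @return `write_regions`: `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  jsonlite::write_json(unclass(regions), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

map_column_key <- function(map, column) {
  r <- map$map[map$map$column == column, ]
  if (!nrow(r)) return(NA_character_)
  r$res_key[1]
}

#' Classify a coevolving pair as direct or mediated compensation
#'
#' A pair in structural contact (min atom distance at or below `cutoff`)
#' is a direct compensatory candidate. Otherwise (pair distance above
#' `indirect_trigger`) conserved sites contacting both members within
#' `cutoff` are sought: any such mediator makes the pair indirect;
#' without one it is unsupported.
#'
#' @param site_a,site_b Alignment column indices of the pair.
#' @param contacts A [contact_map()] of the reference structure.
#' @param conserved A [conservation_profile()] (or integer vector of
#'   conserved alignment columns).
#' @param map An [map_alignment_to_structure()] result.
#' @param cutoff Contact cutoff (Angstrom, default 4.0).
#' @param indirect_trigger Pair distance above which the mediator search
#'   runs (default 4.0; the stricter variant uses 8.0, leaving pairs
#'   between the cutoffs unsupported).
#' @return One-row tibble: site_a, site_b, label_a, label_b, class
#'   (`direct`/`indirect`/`unsupported`/`unmappable`), pair_min_dist,
#'   mediators (list-column of alignment columns), mediator_labels.
#' @export
classify_pair <- function(site_a, site_b, contacts, conserved, map,
                          cutoff = 4.0, indirect_trigger = 4.0) {
  cons_sites <- if (inherits(conserved, "conservation_profile"))
    conserved$conserved_sites else as.integer(conserved)
  ka <- map_column_key(map, site_a); kb <- map_column_key(map, site_b)
  la <- site_label(map, site_a); lb <- site_label(map, site_b)
  base <- tibble(site_a = site_a, site_b = site_b, label_a = la, label_b = lb)
  if (is.na(ka) || is.na(kb))
    return(dplyr::mutate(base, class = "unmappable", pair_min_dist = NA_real_,
                         mediators = list(integer(0)),
                         mediator_labels = ""))
  d <- cm_min_dist(contacts, ka, kb)
  if (d <= cutoff)
    return(dplyr::mutate(base, class = "direct", pair_min_dist = d,
                         mediators = list(integer(0)), mediator_labels = ""))
  meds <- integer(0)
  if (d > indirect_trigger) {
    for (cs in setdiff(cons_sites, c(site_a, site_b))) {
      kc <- map_column_key(map, cs)
      if (is.na(kc)) next
      if (cm_min_dist(contacts, kc, ka) <= cutoff &&
          cm_min_dist(contacts, kc, kb) <= cutoff)
        meds <- c(meds, cs)
    }
  }
  cls <- if (length(meds)) "indirect" else "unsupported"
  dplyr::mutate(base, class = cls, pair_min_dist = d,
                mediators = list(sort(meds)),
                mediator_labels = paste(vapply(sort(meds), function(cc)
                  site_label(map, cc), character(1)), collapse = ","))
}

#' Functional regions contacted by a site
#'
#' For each annotated region, the region residues that the site touches:
#' identical to the site, or with min atom distance within `cutoff`.
#' Regions with no hit are omitted.
#'
#' @param site Reference residue number (1ANG-style numbering).
#' @param contacts A [contact_map()] of the reference structure.
#' @param annotation A [functional_regions()] annotation.
#' @param cutoff Distance cutoff (Angstrom, default 4.0).
#' @param chain Chain id used to build residue keys (default `"A"`).
#' @return Tibble: region, residues (list-column of hit residue numbers).
#' @export
annotate_regions <- function(site, contacts, annotation = functional_regions(),
                             cutoff = 4.0, chain = "A") {
  resnos <- contacts$residues$resno
  key_of <- function(rn) contacts$residues$res_key[match(rn, resnos)]
  ks <- key_of(site)
  if (is.na(ks)) abort(sprintf("residue %d not in structure", site))
  hits <- lapply(names(annotation), function(rg) {
    present <- intersect(annotation[[rg]], resnos)
    got <- present[vapply(present, function(rn)
      rn == site || cm_min_dist(contacts, ks, key_of(rn)) <= cutoff, logical(1))]
    if (length(got)) tibble(region = rg, residues = list(sort(got))) else NULL
  })
  out <- dplyr::bind_rows(hits)
  if (!nrow(out)) tibble(region = character(), residues = list()) else out
}

region_hit_string <- function(site, contacts, annotation, cutoff) {
  hits <- annotate_regions(site, contacts, annotation, cutoff)
  if (!nrow(hits)) return("")
  paste(vapply(seq_len(nrow(hits)), function(i)
    sprintf("%s:%s", hits$region[i], paste(hits$residues[[i]], collapse = "/")),
    character(1)), collapse = ";")
}

#' Compensation report (pairs x groups x structure context)
#'
#' One row per classified coevolving pair: residue-pair label in
#' reference numbering, the coevolution groups containing both members,
#' classification, conserved mediators, region hits for each member and
#' for the mediators, and region hits near either member. Row order is
#' deterministic (by site indices).
#'
#' @param classified Tibble of [classify_pair()] rows.
#' @param groups A [build_groups()] tibble.
#' @param contacts A [contact_map()].
#' @param map An [map_alignment_to_structure()] result.
#' @param annotation A [functional_regions()] annotation.
#' @param cutoff Distance cutoff (default 4.0).
#' @return Tibble (class `compensation_report`).
#' @export
compensation_report <- function(classified, groups, contacts, map,
                                annotation = functional_regions(),
                                cutoff = 4.0) {
  if (!nrow(classified)) {
    out <- tibble(pair = character(), groups = character(), class = character(),
                  pair_min_dist = numeric(), mediators = character(),
                  regions_a = character(), regions_b = character(),
                  regions_mediators = character(), regions_either = character())
    return(structure(out, class = c("compensation_report", class(out))))
  }
  classified <- classified[order(classified$site_a, classified$site_b), ]
  rows <- lapply(seq_len(nrow(classified)), function(i) {
    r <- classified[i, ]
    gid <- groups$group_id[vapply(groups$members, function(m)
      all(c(r$site_a, r$site_b) %in% m), logical(1))]
    resno_of <- function(col) map$map$ref_resno[match(col, map$map$column)]
    ra <- resno_of(r$site_a); rb <- resno_of(r$site_b)
    reg_a <- if (!is.na(ra)) region_hit_string(ra, contacts, annotation, cutoff) else ""
    reg_b <- if (!is.na(rb)) region_hit_string(rb, contacts, annotation, cutoff) else ""
    med_cols <- r$mediators[[1]]
    reg_m <- paste(Filter(nzchar, vapply(med_cols, function(mc) {
      rm_ <- resno_of(mc)
      if (is.na(rm_)) "" else region_hit_string(rm_, contacts, annotation, cutoff)
    }, character(1))), collapse = ";")
    either <- unique(c(strsplit(reg_a, ";")[[1]], strsplit(reg_b, ";")[[1]]))
    tibble(pair = paste0(r$label_a, "-", r$label_b),
           groups = paste(gid, collapse = ","),
           class = r$class, pair_min_dist = r$pair_min_dist,
           mediators = r$mediator_labels,
           regions_a = reg_a, regions_b = reg_b, regions_mediators = reg_m,
           regions_either = paste(Filter(nzchar, either), collapse = ";"))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("compensation_report", class(out)))
}

#' Write a compensation report as TSV or JSON
#'
#' @param report A [compensation_report()].
#' @param path Output path; format chosen by extension (`.json` or TSV
#'   otherwise).
#' @return `path`, invisibly.
#' @export
write_compensation <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
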