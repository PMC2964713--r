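#' Pipeline run configuration
#'
#' Bundles inputs and tuning parameters for [run_pipeline()]. Thresholds
#' mirror the analysis defaults: alpha 0.01 on adjusted coevolution
#' p-values, conservation tail 0.01, contact cutoff 4 Angstrom
#' (inclusive), mediator search triggered above 4 Angstrom (8 available),
#' BLOSUM62 scores.
#'
#' @param protein_fasta,cds_fasta,tree,pdb,regions Input file paths
#'   (regions may be NULL for the bundled defaults).
#' @param ref_taxon Reference taxon for structure numbering (default:
#'   first alignment row).
#' @param out_dir Output directory.
#' @param alpha,n_perm,tail,n_boot,cutoff,indirect_trigger,matrix,seed
#'   Analysis parameters (see the stage functions).
#' @param scan_n_sims Calibration simulations for the selection scan.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(protein_fasta, cds_fasta, tree, pdb,
                            regions = NULL, ref_taxon = NULL,
                            out_dir = tempfile("compevo_run"),
                            alpha = 0.01, n_perm = 1e6, tail = 0.01,
                            n_boot = 1e6, cutoff = 4.0,
                            indirect_trigger = 4.0, matrix = "BLOSUM62",
                            seed = 1L, scan_n_sims = 50L) {
  stopifnot(alpha > 0, alpha < 1, tail > 0, tail < 1, cutoff > 0)
  structure(list(protein_fasta = protein_fasta, cds_fasta = cds_fasta,
                 tree = tree, pdb = pdb, regions = regions,
                 ref_taxon = ref_taxon, out_dir = out_dir, alpha = alpha,
                 n_perm = n_perm, tail = tail, n_boot = n_boot,
                 cutoff = cutoff, indirect_trigger = indirect_trigger,
                 matrix = matrix, seed = as.integer(seed),
                 scan_n_sims = as.integer(scan_n_sims)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains the stages: read inputs, conservation profile, coevolution
#' detection, group construction, structure mapping and contact map,
#' compensatory classification, selection scan, and the final report.
#' Each stage writes its table under `out_dir`; a manifest JSON records
#' inputs, parameters, seed, package version and per-stage row counts.
#' Reruns with the same config and seed reproduce identical tables.
#'
#' @param config A [pipeline_config()].
#' @return List of stage results (invisible file side effects):
#'   `conservation`, `coevolution`, `groups`, `map`, `contacts`,
#'   `classified`, `scan`, `report`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_counts <- list()
  prot <- read_alignment(config$protein_fasta, "protein")
  cds <- read_alignment(config$cds_fasta, "nucleotide")
  caln <- backtranslate(prot, cds)
  tree <- as_phylo(config$tree)
  model <- parse_structure(config$pdb)
  annotation <- if (is.null(config$regions)) functional_regions()
                else read_regions(config$regions)
  ref <- config$ref_taxon %||% prot$taxa[1]

  cons <- conservation_profile(prot, n_boot = config$n_boot,
                               tail = config$tail,
                               seed = derive_seed(config$seed, "conserve"))
  write_conservation_tsv(cons, file.path(config$out_dir, "conservation.tsv"))
  stage_counts$conserve <- nrow(cons$sites)

  coev <- detect_coevolution(prot, caln, tree, alpha = config$alpha,
                             matrix = config$matrix, n_perm = config$n_perm,
                             seed = derive_seed(config$seed, "coevolve"))
  stage_counts$coevolve <- nrow(coev$pairs)
  groups <- build_groups(coev)
  stage_counts$groups <- nrow(groups)

  map <- map_alignment_to_structure(prot, ref, model)
  cm <- contact_map(model, cutoff = config$cutoff)
  write_coevolution_tsv(coev, file.path(config$out_dir, "coevolution.tsv"),
                        map = map)
  write_coevolution_tsv(groups, file.path(config$out_dir, "groups.tsv"))
  stage_counts$map_structure <- sum(!is.na(map$map$ref_resno))

  sig <- coev$pairs[coev$pairs$significant, ]
  classified <- dplyr::bind_rows(lapply(seq_len(nrow(sig)), function(i)
    classify_pair(sig$site_a[i], sig$site_b[i], cm, cons, map,
                  cutoff = config$cutoff,
                  indirect_trigger = config$indirect_trigger)))
  stage_counts$compensate <- nrow(classified)

  calib <- calibrate_null(tree, n_codons = ncol(caln$codons),
                          n_sims = config$scan_n_sims,
                          seed = derive_seed(config$seed, "scan_calibration"),
                          alpha = config$alpha)
  scan <- scan_selection(caln, tree, calib)
  write_scan_tsv(scan, file.path(config$out_dir, "selection_scan.tsv"))
  stage_counts$scan <- nrow(scan$windows)

  report <- compensation_report(classified, groups, cm, map, annotation,
                                cutoff = config$cutoff)
  write_compensation(report, file.path(config$out_dir, "compensation.tsv"))
  write_compensation(report, file.path(config$out_dir, "compensation.json"))
  stage_counts$report <- nrow(report)

  manifest <- list(
    package = "compevo",
    version = as.character(utils::packageVersion("compevo")),
    inputs = config[c("protein_fasta", "cds_fasta", "tree", "pdb", "regions")],
    parameters = config[c("alpha", "n_perm", "tail", "n_boot", "cutoff",
                          "indirect_trigger", "matrix", "scan_n_sims")],
    seed = config$seed, ref_taxon = ref,
    stages = stage_counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(conservation = cons, coevolution = coev, groups = groups,
                 map = map, contacts = cm, classified = classified,
                 scan = scan, report = report, manifest = manifest))
}

#' Run a single pipeline stage by name
#'
#' Functional equivalent of a `compevo <stage>` subcommand: `simulate`
#' writes the toy fixture; the analysis stages run [run_pipeline()]'s
#' components individually; `all` chains everything.
#'
#' @param name One of `simulate`, `conserve`, `coevolve`, `scan`,
#'   `map-structure`, `compensate`, `report`, `all`.
#' @param config A [pipeline_config()] (ignored by `simulate`).
#' @param ... Passed to [make_fixture()] for `simulate`.
#' @return Stage result (see the stage functions).
#' @export
run_stage <- function(name, config = NULL, ...) {
  stages <- c("simulate", "conserve", "coevolve", "scan", "map-structure",
              "compensate", "report", "all")
  if (!name %in% stages)
    abort(sprintf("unknown subcommand '%s' (expected one of: %s)", name,
                  paste(stages, collapse = ", ")),
          class = "compevo_usage_error")
  if (name == "simulate") return(make_fixture(...))
  stopifnot(inherits(config, "pipeline_config"))
  if (name == "all") return(run_pipeline(config))
  prot <- read_alignment(config$protein_fasta, "protein")
  switch(name,
    conserve = conservation_profile(prot, n_boot = config$n_boot,
                                    tail = config$tail,
                                    seed = derive_seed(config$seed, "conserve")),
    coevolve = {
      cds <- read_alignment(config$cds_fasta, "nucleotide")
      detect_coevolution(prot, backtranslate(prot, cds),
                         as_phylo(config$tree), alpha = config$alpha,
                         matrix = config$matrix, n_perm = config$n_perm,
                         seed = derive_seed(config$seed, "coevolve"))
    },
    scan = {
      cds <- read_alignment(config$cds_fasta, "nucleotide")
      caln <- backtranslate(prot, cds)
      tree <- as_phylo(config$tree)
      calib <- calibrate_null(tree, n_codons = ncol(caln$codons),
                              n_sims = config$scan_n_sims,
                              seed = derive_seed(config$seed, "scan_calibration"),
                              alpha = config$alpha)
      scan_selection(caln, tree, calib)
    },
    `map-structure` = map_alignment_to_structure(
      prot, config$ref_taxon %||% prot$taxa[1], parse_structure(config$pdb)),
    compensate = ,
    report = run_pipeline(config))
}
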