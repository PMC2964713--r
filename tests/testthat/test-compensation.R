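# A fully planted toy: contact pair (2,7), mediated pair (3,9) via
# mediator 5, everything mapped 1:1 to a 10-residue structure.
toy_setup <- function(seed = 3) {
  st <- simulate_structure(10, planted_contacts = rbind(c(2, 7)),
                           planted_mediators = rbind(c(3, 9, 5)), seed = seed,
                           residue_names = c("M", "K", "D", "A", "N",
                                             "G", "K", "T", "H", "L"))
  aln <- protein_alignment(c(ref = "MKDANGKTHL", o1 = "MRDANGITHL",
                             o2 = "MKEANGKSHL", o3 = "MRDANGITHI"))
  map <- map_alignment_to_structure(aln, "ref", st$model)
  cm <- contact_map(st$model)
  list(st = st, aln = aln, map = map, cm = cm)
}

test_that("classification separates direct, indirect and unsupported pairs", {
  tc <- toy_setup()
  conserved <- c(5L)
  direct <- classify_pair(2, 7, tc$cm, conserved, tc$map)
  expect_identical(direct$class, "direct")
  expect_lte(direct$pair_min_dist, 4)

  indirect <- classify_pair(3, 9, tc$cm, conserved, tc$map)
  expect_identical(indirect$class, "indirect")
  expect_identical(indirect$mediators[[1]], 5L)
  expect_identical(indirect$mediator_labels, "N5")

  # same pair without the mediator in the conserved set -> unsupported
  unsup <- classify_pair(3, 9, tc$cm, integer(0), tc$map)
  expect_identical(unsup$class, "unsupported")

  # symmetry in the two sites
  swapped <- classify_pair(9, 3, tc$cm, conserved, tc$map)
  expect_identical(swapped$class, indirect$class)
  expect_identical(swapped$mediators[[1]], indirect$mediators[[1]])
  expect_equal(swapped$pair_min_dist, indirect$pair_min_dist)
})

test_that("shrinking the conserved set only moves pairs toward unsupported", {
  tc <- toy_setup()
  full <- classify_pair(3, 9, tc$cm, c(5L, 6L), tc$map)
  shrunk <- classify_pair(3, 9, tc$cm, 6L, tc$map)
  expect_identical(full$class, "indirect")
  expect_true(shrunk$class %in% c("indirect", "unsupported"))
  expect_true(all(shrunk$mediators[[1]] %in% full$mediators[[1]]))
})

test_that("the stricter indirect trigger leaves mid-range pairs unsupported", {
  tc <- toy_setup()
  d <- classify_pair(3, 9, tc$cm, 5L, tc$map, indirect_trigger = 8)$pair_min_dist
  got <- classify_pair(3, 9, tc$cm, 5L, tc$map, indirect_trigger = 8)
  if (d <= 8) expect_identical(got$class, "unsupported")
  else expect_identical(got$class, "indirect")
})

test_that("mediators re-check against the contact map", {
  tc <- toy_setup()
  cl <- classify_pair(3, 9, tc$cm, c(5L), tc$map)
  ka <- compevo:::map_column_key(tc$map, 3)
  kb <- compevo:::map_column_key(tc$map, 9)
  for (med in cl$mediators[[1]]) {
    km <- compevo:::map_column_key(tc$map, med)
    expect_lte(compevo:::cm_min_dist(tc$cm, km, ka), 4)
    expect_lte(compevo:::cm_min_dist(tc$cm, km, kb), 4)
  }
})

test_that("region annotation uses identity and proximity", {
  tc <- toy_setup()
  ann <- functional_regions(list(active_site = c(2L, 9L), B1 = 7L))
  # a region member hits its own region at distance zero
  hits <- annotate_regions(2, tc$cm, ann)
  expect_true("active_site" %in% hits$region)
  expect_true(2 %in% hits$residues[[which(hits$region == "active_site")]])
  # the planted contact partner (7) is within 4 A of residue 2
  hits7 <- annotate_regions(7, tc$cm, ann)
  expect_true("active_site" %in% hits7$region)
  # a far residue returns an empty hit list for a distant-only annotation
  far <- annotate_regions(9, tc$cm, functional_regions(list(only = 1L)))
  expect_equal(nrow(far), 0)
})

test_that("the report mirrors the classification with deterministic rows", {
  tc <- toy_setup()
  classified <- dplyr::bind_rows(
    classify_pair(2, 7, tc$cm, 5L, tc$map),
    classify_pair(3, 9, tc$cm, 5L, tc$map))
  groups <- build_groups(tibble::tibble(site_a = c(2, 3), site_b = c(7, 9)))
  ann <- functional_regions(list(active_site = c(2L, 9L), B1 = 7L))
  rep1 <- compensation_report(classified, groups, tc$cm, tc$map, ann)
  expect_equal(nrow(rep1), 2)
  expect_identical(rep1$pair, c("K2-K7", "D3-H9"))
  expect_identical(rep1$class, c("direct", "indirect"))
  expect_identical(rep1$mediators, c("", "N5"))
  expect_true(all(nzchar(rep1$groups)))

  # empty input -> header-only report
  rep0 <- compensation_report(classified[0, ], groups, tc$cm, tc$map, ann)
  expect_equal(nrow(rep0), 0)

  # TSV and JSON round trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_compensation(rep1, tsv)
  write_compensation(rep1, js)
  expect_equal(nrow(read.delim(tsv)), 2)
  expect_equal(length(jsonlite::read_json(js)), 2)
})

test_that("region config round-trips through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  ann <- functional_regions()
  write_regions(ann, path)
  back <- read_regions(path)
  expect_equal(back$active_site, c(13L, 40L, 114L))
  expect_equal(back$NLS, 31:35)
})
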