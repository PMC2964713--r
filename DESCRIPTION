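Package: compevo
Title: Coevolving and Compensatory Residue Pairs in Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects intramolecular coevolving amino-acid site pairs with a
    divergence-time-corrected substitution-score correlation and a
    permutation null with step-down multiple-testing correction; classifies
    coevolving pairs as direct or mediated compensatory pairs using
    structural contact maps at a 4 Angstrom cutoff and conserved mediator
    sites from a per-site Poisson-divergence bootstrap; scans branches of a
    phylogeny for selective constraints with a sliding-window dS/dN test
    (Li 1993 counting, Poisson expectations calibrated on simulated
    alignments); and provides supporting measures (codon adaptation index,
    residue mass-centre RMSD) plus a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    seqinr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
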