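---
title: "Detecting coevolving and compensatory residue pairs in duplicated genes"
author: "compevo"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compevo)
```

## The scientific problem

After a gene duplicates, the copies diverge under shifting selective
constraints. Two signatures of that process are visible in a codon
alignment of the family: *coevolving* residue pairs, whose substitutions
track each other across the phylogeny because a change at one site is
compensated by a change at the other, and *branch-specific selective
constraints*, codon regions whose nonsynonymous rate on particular
branches departs from the family background. Angiogenin-like families —
a tandemly duplicated ribonuclease with a catalytic triad, receptor
binding subsites and a nuclear localization signal — are the motivating
system: compensatory candidates are coevolving pairs that are also close
in the protein structure (within 4 Å), or that both touch a strongly
conserved third residue, and their functional relevance is read off
their proximity to the annotated regions.

`compevo` implements that entire analysis as a tested pipeline:
conservation profiling, coevolution detection with a permutation null
and step-down correction, a sliding-window dS/dN selection scan,
structural contact and RMSD geometry, compensatory classification, and a
synthetic-data generator that plants known coevolving pairs, selected
windows and structural contacts so every stage can be validated against
ground truth.

## Per-site conservation

For an alignment column the fraction `p` of sequence pairs that differ
(gap and unknown residues skipped pairwise) is corrected for multiple
hits with the Poisson distance `d = -ln(1 - p)`; a fully saturated
column (`p = 1`) is capped at `-ln(1/(2 n_pairs))` and flagged. The
"conserved" call compares each site with the alignment's own
distribution: columns are bootstrapped with replacement (default one
million draws) and a site is conserved when its `d` lies at or below the
lower 1% quantile (the tail is configurable; ties are inclusive, so
invariant columns always qualify whenever any threshold is produced).
The per-column pair-fraction definition is one of several possible
pairing schemes; it is the natural exchangeable choice and invariant
under row permutation. Columns with fewer than two usable residues are
uninformative: excluded from the bootstrap and never called conserved.

```{r conservation-example}
aln <- protein_alignment(c(a = "MKACDE", b = "MKACDQ", c = "MRACDE",
                           d = "MRACDQ"))
prof <- conservation_profile(aln, n_boot = 1e4, tail = 0.01, seed = 1)
tidy(prof)
```

## The coevolution statistic

The model is correlated evolution of substitution *rates* at two sites,
corrected for the time each part of the tree represents. The package
works on the branches of the phylogeny:

1. Ancestral codon sequences are reconstructed by nucleotide-level
   Fitch parsimony (deterministic, ties resolved alphabetically and
   flagged).
2. Every branch × site cell records whether the amino acid changed
   (optionally the BLOSUM exchange-score magnitude of the change;
   `score = "blosum"`).
3. Each branch's mean across sites is removed. This is the divergence
   correction: a branch representing more evolutionary time accumulates
   more change at every site, and subtracting the branch effect leaves
   site-specific excesses. Per-branch synonymous divergence — the
   classical proxy for branch time — is reported alongside
   (`t_branch`).
4. Site vectors are centred, and a site pair's correlation `rho` is the
   Pearson correlation of the two centred profiles across branches.

The *test* statistic, however, is the centred covariance, not `rho`. A
correlation saturates at 1 as soon as two sites coincide on a single
branch by phylogenetic chance, so it cannot distinguish one lucky
coincidence from five coupled co-substitutions; the covariance grows
with the number of co-substitution branches, which is exactly what
repeated compensatory evolution produces. Both quantities are reported
per pair.

A sequence-pair formulation in the classical style — transition scores
`B(a_ik, a_il) / t_kl` residual-centred and correlated across sequence
pairs — is retained as `caps_residuals()` / `caps_correlation()`.
Development measurements showed it cannot be calibrated on
phylogenetically structured alignments: the shared `1/t_kl` factor (and
its floor at `1e-4` for identical pairs) concentrates the correlation's
weight on a handful of near-zero-divergence pairs, and deep-branch
bipartitions enter the pair space quadratically, so unrelated site
pairs reach `|rho| ~ 1` by chance while no data permutation reproduces
that coincidence distribution. The branch formulation keeps the same
ingredients (substitution scores, synonymous-divergence time proxy,
Pearson correlation) with one observation per branch, where the
permutation null below is exact.

### Tested sites

Only sites with at least `min_changes = 3` reconstructed changes enter
the tested pair family. This is independent filtering in the DESeq2
sense: a site with one or two changes cannot reach familywise
significance at `alpha = 0.01` — a single shared branch is far too
likely by chance — so testing such pairs only enlarges the family and
costs power for the testable ones. The filter statistic (per-site change
count) is independent of the pair-level permutation null.

### Null distribution and multiplicity

Each null replicate applies one random permutation of the branch index
to one member of every tested pair, preserving each site's change count
and magnitude profile while destroying shared placement; with
`B = max(200, ceiling(n_perm / n_pairs))` replicates the pooled draws
(at least `n_perm`, default one million; tests use ten thousand) give
raw p-values, and the per-replicate family maxima drive a
Westfall–Young-style step-down: pairs are ordered by decreasing
statistic and each adjusted p-value is the fraction of replicates whose
maximum over the pair and all less-significant pairs reaches the
observed value, with monotonicity enforced and `p_adj >= p_raw`.
Significant pairs (default `alpha = 0.01`) are grouped into maximal
cliques (`build_groups()`): a group contains only sites each pair of
which coevolves, and one site may belong to several groups.

Physico-chemical annotation (`property_filter()`) correlates, per pair
and residue scale (Kyte–Doolittle hydropathy and residue mass by
default), the per-observation magnitudes of property change — an
annotation by default, not a hard filter.

### Operating characteristics

On neutral simulated alignments (15 taxa × 100 codons, the generator's
default conditions) the acceptance suite measures a mean significant
fraction of about 0.2% with 19–20 of 20 alignments reporting zero
significant pairs — the familywise error is controlled. Sensitivity to
planted pairs at coupling 0.9 under those same conditions is low
(roughly 10–15% at familywise `p_adj <= 0.01`): with 15 taxa the tree
has only 28 branches, and a planted pair whose driver substituted on
`k ~ 5–8` branches is separable from the maximum of hundreds of chance
hypergeometric overlaps only when nearly all co-substitutions are
recovered on the correct branches, which the 10% coupling failures and
parsimony misplacement prevent. Even an oracle given the true
substitution histories reaches only ~60% under these conditions. Ranking
behaves much better: planted pairs dominate the top of the statistic
ordering, with few or no chance pairs above the planted median. Users
should read the method's significant calls as high-precision,
low-recall on families of this size; more taxa widen the branch space
and lift both.

## The selection scan

For each branch of the tree (ancestral sequences again from Fitch
parsimony; codons touched by an arbitrarily resolved nucleotide are
excluded from counts), substitutions are counted per codon and classed
synonymous/nonsynonymous by whether the amino acid changed. A window of
`w` codons slides in steps of one; per window the scan reports Li
(1993) dS/dN — degeneracy classes 0/2/4-fold averaged over the two
codons, transitions/transversions counted per class, Kimura
two-parameter corrections combined with the Li weighting — plus Poisson
tail probabilities of the observed counts against calibrated
expectations, and a classification:

* `positive_selection`: nonsynonymous excess significant and `dN > dS`;
* `hotspot`: nonsynonymous and synonymous excess both significant;
* `accelerated_dN`: nonsynonymous excess significant, `dN <= dS`;
* `negative_selection`: nonsynonymous count significantly *below*
  expectation (lower tail);
* `neutral` otherwise; `untestable` when no codon is comparable. A
  window with `dS = 0` and `dN > 0` reports omega as an `inf` flag, not
  a number.

Calibration (`calibrate_null()`) simulates neutral alignments on the
same tree (default 50), fits per-branch Poisson rates, and sets the
familywise significance threshold just below the smallest window
p-value seen across the simulations, so a fully neutral alignment
produces any significant window with probability of roughly
`1/(n_sims + 1)`. The window size is then chosen, among candidates that
meet the false-positive criterion (all of them, under their own
calibrated thresholds), as the one needing the smallest per-codon
substitution excess for a call — the most sensitive. Acceptance
measurements: a planted `omega = 5` window of 15 codons on an internal
branch of an 8-taxon tree is recovered in ≥80% (typically 100%) of
replicates, while on fully neutral replicates under 2% of branches show
any positive call. Branches adjacent to the root are blind spots — with
no outgroup, parsimony cannot polarise changes across the root, so
their substitutions are ambiguity-masked; plant and interpret
accordingly.

## Structure, contacts and compensation

PDB files are parsed with bio3d (heavy atoms only; first altloc;
waters, hydrogens and HETATM dropped; insertion codes kept in residue
keys). The inter-residue distance is the plain average over all atom
pairs, `d = (1/(N K)) sum_i sum_j ||a_i - b_j||`; contact means minimum
atom distance at or below 4 Å, inclusive, and both the cutoff and the
variant 8 Å indirect trigger are configurable. Residue mass centres are
mass-weighted by default (geometric centres optional); mass-centre RMSD
between two structures optionally applies Kabsch superposition first —
the default, since compared homology models live in arbitrary frames —
and superposition can be disabled to measure displacement within a
shared frame.

Alignment columns map to reference-structure residue numbers through
the reference taxon's row: equal-length cases map sequentially,
otherwise a Needleman–Wunsch alignment (Biostrings) absorbs residues
missing from density; mismatched residue names are kept with a warning,
and a sub-50% match rate errors. All reported site labels use the
reference numbering with one-letter prefixes ("D41").

A significant coevolving pair is classified `direct` when its minimum
atom distance is within the cutoff; otherwise conserved sites within
the cutoff of *both* members are sought and any hit makes the pair
`indirect` with those mediators listed; with neither the pair is
`unsupported`. The mediator search triggers for any pair beyond the
contact cutoff (the stricter variant, triggering only beyond 8 Å, is the
`indirect_trigger` option). The report annotates each member and
mediator with the functional regions it touches (identity counts as
distance zero); the bundled defaults are the angiogenin regions in
reference numbering — catalytic triad 13/40/114, B1 44/118, B2 108, P2
5/8, the nuclear localization signal 31–35, and the putative
cell-binding segment — and any region set can be supplied as JSON.

## The synthetic-data generator

`simulate_alignment()` runs a Gillespie codon process along each branch:
per-codon single-nucleotide rates with transition bias `kappa` (default
2), nonsynonymous targets scaled by `omega` (default 0.4), stops
excluded, so `omega > 1` is a genuine rate excess rather than an
acceptance probability. Planted windows raise omega locally on one
branch. Planted pairs couple mechanistically: the driver site evolves at
`driver_omega` (default 2, the relaxed/episodically adaptive regime
expected of compensating sites) and its partner substitutes *only*
through coupling — on each branch where the driver fixed a
nonsynonymous change, the partner co-substitutes with probability
`rho`, choosing a target that does not revert its pre-branch state.
Random trees take exponential branch lengths with mean 0.05
substitutions/site: deep enough that sites substitute repeatedly,
shallow enough (total tree length near 1.4) that parsimony
reconstruction stays reliable. The generator emulates the calibration
role the original analysis delegated to a codon-model simulator; it is
a mutation-level process, not a likelihood model, and is suitable for
calibration and power measurement, not inference.

`simulate_structure()` grows a self-avoiding chain (3.8 Å steps, 3.0 Å
clash floor) of three-pseudo-atom residues — three atoms so mean- and
min-distance operators differ measurably — then pulls planted contact
pairs within reach, places mediator triples in the
"apart-but-bridged" geometry, verifies every planted predicate with the
structure module itself (including that no stray residue bridges a
mediated pair) and retries from a derived seed when geometry fails.
`make_fixture()` bundles a deterministic 12-taxon, 60-codon dataset
with two planted coevolving pairs (one in contact, one mediated by a
planted invariant site), one planted `omega = 5` window, three
invariant columns, the matching toy structure and ground-truth JSON;
regenerating it is byte-identical.

What passing tests on these synthetics do *not* show: real alignments
bring alignment error, heterotachy, indel structure, biased codon usage
and model misspecification that the generator does not emulate, and
real structures bring conformational flexibility the 4 Å crystal
criterion ignores.

## Numerical choices and degenerate inputs

* Divergence floor `epsilon = 1e-4` and saturation cap 5
  substitutions/site in the pairwise synonymous distance matrix, both
  flagged.
* Fitch ties resolve alphabetically and are flagged; flagged codons are
  excluded from scan counts but kept (resolution accepted) in
  coevolution profiles, where discarding them was measured to erase
  most of the change signal at fast sites.
* Zero-variance site vectors correlate as 0 by definition; pairs with
  fewer than 6 shared observations are untestable.
* The conservation quantile is the empirical (type 1) quantile, so the
  threshold is always an attained value.
* Poisson window tests use counts, not distances; `dS`/`dN` are
  reported per window for interpretation.
* One user seed fans out to per-stage derived seeds; every stochastic
  stage is reproducible from the run manifest.

## Problem sizes used by the test-suite and acceptance measurements

Simulation-based checks run at 15 taxa × 100 codons with ten thousand
permutation draws and twenty neutral replicates for coevolution
calibration; five (tests) or three (acceptance script) planted
replicates for sensitivity; twenty (tests) or ten (script) replicates
with fifty calibration simulations each for the selection scan; and one
hundred thousand bootstrap draws for conservation checks. These sizes
give Monte-Carlo error comfortably inside the asserted tolerances while
keeping a full run in minutes; the package defaults (one million draws)
match the analysis scale the pipeline is meant for.
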