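---
title: "Peptide pattern recognition: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide pattern recognition: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Peptide pattern recognition (PPR) classifies proteins without alignment.
Its unit of information is the conserved *hexapeptide*: a 6-residue
substring shared across members of a family because it sits in or near
functionally constrained sequence (in the motivating enzyme family, CE15
carbohydrate esterases, around the Ser–His–Glu catalytic triad). A family,
or *group*, is represented by a ranked list of its most widespread
hexapeptides, capped at 70; a protein belongs to the group when it contains
at least 10 distinct list peptides. These three numbers — peptide length 6,
10 peptides per protein, 70 peptides per group — are the published settings
for the CE15 analysis and are the package defaults (`ppr_params()`), but all
are tunable.

Conservation is measured by *protein presence*, not occurrence count: a
peptide found twice in one sequence still counts once. This matches the
intent of "conserved among input sequences" and makes scores integers
bounded by the list size.

### Clustering

The published analyses cite the PPR software without restating its inner
loop, so the grouping procedure here is this package's own deterministic
reconstruction of the stated contract — groups of proteins sharing a
bounded list of conserved peptides, every member containing at least the
membership threshold:

1. *Seed*: find the single peptide contained in the most proteins (ties
   broken lexicographically); the seed members are all proteins containing
   it.
2. *Refine*: derive the member set's top-70 peptide list, then redefine the
   members as **all** unassigned proteins containing ≥ 10 list peptides.
   Repeat until the member set repeats.
3. *Terminate*: a revisited state that is not a fixed point means the
   iteration oscillates; the visited state with the most members (earliest
   on ties) is kept. The reported member set is always the score-filter of
   the reported list, so the membership contract holds by construction.
4. *Iterate*: accept the group if it has ≥ 2 members (`min_group_size`),
   remove its members, and start again; stop at the first failure, leaving
   the remainder unclassified.

The result is a partition: every input protein lands in exactly one group
or in the unclassified set, and reruns on identical input are identical.
Alternative seeding schemes (random restarts, all-against-all sharing)
would fit behind the same `form_group()` interface; single-peptide seeding
was chosen because it is deterministic and auditable. One protein can
belong to only one group — the strict-partition reading of "divided into
groups".

### Annotation and the genome scan

`annotate_proteins()` scores a sequence against every group list (distinct
list peptides contained) and assigns the unique argmax if it reaches
`min_score`; ties are reported as `ambiguous`, sub-threshold maxima as
`unassigned`. The default `min_score = 5` is a package choice, not a
published value: it sits well below the 10-peptide membership criterion yet
orders of magnitude above random 6-mer collision noise (a 60-residue random
segment matches a 70-peptide list with expected count ≈ 55 × 70 / 20⁶ ≈
6 × 10⁻⁵), and the negative-control benchmark verifies that random DNA
yields zero assignments at this threshold.

`scan_genome()` reproduces the published crude genome screen: split the
genome into 2000-base fragments overlapping by 100 bases, translate each in
all six frames, and keep every stop-free translated segment of ≥ 51
residues ("longer than 50 residues"), with no start-codon requirement.
Interpretation choices, fixed here and testable:

* Segments are stop-to-stop; segments truncated by a fragment edge are kept
  if long enough (the method cannot see past fragment ends).
* Coordinates are 0-based half-open on the forward strand; each hit also
  carries fragment offset and frame, and retranslating the reported
  interval reproduces the peptide exactly (a tested round-trip).
* A segment rediscovered in the 100-base overlap of the next fragment
  (same strand and coordinates) is collapsed: the overlap exists to rescue
  boundary genes, not to double-count them.
* Codons containing `N` translate to `X`; `X` is kept in the peptide but
  never matches a list peptide. The first codon of a frame is translated
  as an ordinary codon, not as an initiator.

### Positional statistics and the serine motif

The position of a conserved hexapeptide is the **median over the sequences
containing it of the 1-based start of its first occurrence**. The median —
rather than the mean — compensates for unequal sequence lengths and
truncated database entries; the even-count median is the mean of the two
central values and may be half-integer. First occurrence is this package's
choice for the (rare, unstated) case of a peptide recurring within one
sequence: one position per sequence is needed for a median over sequences.
`position_histogram()` bins these medians ([1, w], [w+1, 2w], ...; default
width 20 residues, configurable — no published bin width exists).

`find_serine_motifs()` scans peptide lists for the 4-residue pattern
G-x-S-x, the nucleophile-elbow context of the catalytic serine in
alpha/beta-hydrolases (observed variants include GHSF, GHSY, GRSG, GCSG,
GESG, GISL, GISG, GNSG, GHSL, GMSM, GMSL). Every matching (peptide, offset)
window is reported. Locating the catalytic His/Glu is out of scope: in the
motivating study those were placed by structural alignment, not by a stated
computation.

### Pairwise identity

`global_identity()` uses exact Needleman–Wunsch global alignment
(BLOSUM62; gap opening 10, gap extension 0.5, a length-k gap costing
10 + 0.5k) rather than a heuristic multiple aligner, so results are fully
specified and reproducible. Percent identity counts identical residue
pairs over columns where **both** sequences have residues — gap columns are
excluded from the denominator. Other conventions (full alignment length,
shorter-sequence length) shift values by a few percent on 30–60%-identical
sequences; the convention is a documented argument of the method, and the
alignment is verified exactly against an exhaustive enumeration oracle on
short sequences.

## The synthetic benchmark

`generate_families()` emulates the statistical structure PPR assumes: each
family has a random consensus (default 300 residues); members copy it,
mutating residues outside the conserved region with probability 0.5 and
inside it with probability 0 (mutations always change the residue). The
default conserved region is a single 40-residue window at positions
[160, 200), mirroring the conservation hotspot reported for the esterase
families; it guarantees 35 fully conserved hexapeptide windows per family —
comfortably above the 10-peptide membership threshold, and enough for
saturated 70-peptide lists only when a second block is added, which
`generate_families(..., peptides_per_group =)` checks and refuses loudly
otherwise. Record ids are assigned in shuffled order so they encode nothing
about the planted labels.

`generate_genome()` reverse-translates stop-free peptides with uniformly
random synonymous codons, flanks each gene with stop codons, places it on a
random strand, and separates genes with random intergenic DNA, recording
exact coordinates as ground truth.

What the generator does **not** model: indels, rate heterogeneity across
sites and lineages, phylogenetic correlation between members, codon-usage
bias, and real intergenic composition. Passing benchmarks therefore
demonstrate that the algorithms implement their contracts and that planted
signal of the assumed form is recovered essentially perfectly; they do not
certify recovery rates on real, indel-rich families, where conserved
hexapeptides can be disrupted and group counts depend on curation.
Published headline figures that derive from a specific 2015 database
snapshot plus manual curation (115 seed proteins, 1024 curated sequences,
24 groups, per-organism-class averages) are inputs of that provenance, not
reproducible targets; the package reproduces the method, and its
benchmarks check the method's properties.

## Numerical and design choices

* Duplicate removal during curation compares full sequences, not
  accessions (pooled homology hits share sequences under different ids);
  curation order is deduplicate → length filter (≥ 51 residues), with
  logged counts.
* Non-standard residues (B, Z, J, U, O, ambiguity codes) map to `X`, and
  peptides containing `X` are neither counted, listed, nor matched —
  conservative matching that prevents spurious motif hits.
* All tie-breaks (peptide ranking, seed choice) are lexicographic, making
  every stage deterministic; `ppr_cluster()` needs no seed at all, and the
  generators require an explicit one (no hidden global RNG state).
* Benchmark problem sizes (3 families × 20 members, 20 replicate seeds,
  genomes of a few tens of kilobases) were chosen as the smallest sizes at
  which random hexapeptide collisions are measurable yet family signal is
  unambiguous — the same regime the method targets in practice.
* The package is driven from R: `run_pipeline()` plus the exported
  module functions are the interface, and `scripts/acceptance.R` is the
  reproducible end-to-end entry point. TSV reports with fixed sort keys
  and a persisted YAML config make reruns byte-identical and diff-able.

## Known limitations

* The seed-and-refine loop is greedy: formation order can matter for
  overlapping families (real overlapping-signal cases would need the
  multi-membership variant explicitly excluded here).
* `min_score` for genome annotation trades sensitivity for specificity;
  with very short ORFs (just above 51 residues) a true gene fragment can
  score below 5 while still being family-derived.
* Genes straddling fragment boundaries longer than the 100-base overlap
  are systematically missed — a property of the published fragmentation
  scheme itself, preserved deliberately.
* `global_identity()` fixes one alignment convention; comparisons against
  identities computed under other conventions carry a few percent of
  method noise.
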