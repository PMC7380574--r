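---
title: "Dereplicating metagenome-assembled genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dereplicating metagenome-assembled genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magderep)
```

## The problem

Assembling and binning each sample of a series independently is usually the
right call for recovering metagenome-assembled genomes (MAGs): co-assembly
of samples that contain closely related strains fragments badly. The price
is that the same species is recovered again and again across samples, so
the final genome catalogue carries many near-identical MAGs. Redundancy has
two concrete costs. When reads are mapped back against the catalogue, a
read from an abundant population matches several database genomes equally
well; mappers then either spread the reads across the copies or report one
random placement, and every copy looks artificially scarce. And any
quality- or coverage-based curation becomes unreliable, because coverage is
split unevenly across the redundant genomes.

Dereplication removes genomes that are redundant with a retained
representative. `magderep` implements a two-stage approach: a fast MinHash
pre-clustering to avoid all-versus-all alignment, then an accurate
fragment-based average nucleotide identity (ANI) within each pre-cluster,
with a bidirectional ANI-and-coverage rule deciding redundancy and a
quality score choosing representatives.

## Stage 1: MinHash sketches and pre-clusters

Each genome is reduced to a bottom-`s` MinHash sketch: the `s = 1000`
smallest 64-bit hashes over its canonical 21-mers (the lexicographic
minimum of each k-mer and its reverse complement; k-mers containing `N` are
skipped). The hash is a fixed splitmix64 mix of the 2-bit-packed canonical
k-mer with a constant seed, so sketches are bit-identical across machines
and runs — the platform hash function is never used. The Jaccard similarity
of two k-mer sets is estimated on the merged bottom-`s'` set
(`s' = min(s, |union|)`), the unbiased bottom-sketch convention, and
converted to a distance with the Poisson model
`d = -ln(2j / (1 + j)) / k`, capped at 1 for `j = 0`.

The distance matrix is clustered agglomeratively (average linkage by
default; `stats::hclust` does the agglomeration after genomes are sorted by
id, which makes the tree independent of input order). Flat pre-clusters are
cut with the inconsistency criterion at threshold 2 and depth 2: for each
merge the coefficient is `(height - mean) / sd` over the merge heights
within two levels below it (sample standard deviation; zero spread gives
coefficient zero), and a cluster is a maximal subtree in which no merge
exceeds the threshold. This reproduces the flat-cluster extraction of the
SciPy routine commonly scripted for this stage, and the package's tests
cross-check both the coefficients and the resulting partitions against
SciPy directly.

One property of this criterion deserves emphasis, because it is
counter-intuitive: the inconsistency coefficient is scale-free. When a set
contains a few well-separated blocks, the top merges all happen at about
the same (large) height, their local height statistics are homogeneous, and
their coefficients stay *below* 2 — so clearly separated blocks can remain
in a single pre-cluster. We verified this behaviour numerically against
SciPy; it is a property of the criterion, not an implementation artifact.
It is also harmless for correctness: pre-clustering only limits which pairs
proceed to the (more expensive) ANI stage, and the ANI thresholds make the
actual dereplication decisions. Users who want the pre-clusters themselves
to track genome groups should use `criterion = "distance"` with a Mash
distance threshold (0.05 works well for species-level grouping); the
planted-structure recovery tests use exactly that configuration.

## Stage 2: fragment ANI with alignment coverage

Within each pre-cluster every genome pair is compared in both directions.
The query is cut into consecutive 1020-bp windows (a trailing window is
kept when at least 100 bp), following the fragment convention of
BLAST-based genome-wide ANI. For each fragment, candidate subject loci are
found through shared exact 15-mers on both strands; isolated single seeds
are ignored, since a lone shared 15-mer between unrelated sequences is
chance. Each candidate diagonal is scored by a banded local alignment
(band width `0.2 x 1020` bp around the seeded diagonal; match +1, mismatch
-1, gap -2). Identity is matches divided by alignment columns with indel
columns counted as mismatches, and a hit is accepted when identity reaches
30% over at least 70% of the fragment — the ortholog-style acceptance rule.
Local (rather than end-anchored) alignment semantics matter here: when only
part of a fragment has a homolog in the subject (a contig break, an
inserted segment), the alignment covers just that part and the 70%-length
rule rejects the fragment instead of letting unrelated flanks poison the
identity average.

Two exact shortcuts keep this affordable without changing results. A
fragment whose seeds all fall on one diagonal, that fits inside the
contig, and whose ungapped identity is high with clean ends, is scored
ungapped — a gapped alignment cannot beat it there. A fragment whose seeds
fall on exactly two diagonals carries a single indel, and the optimal
one-breakpoint alignment is computed in linear time from prefix/suffix
match sums; the full banded DP runs only when neither shortcut's
preconditions hold (multiple indels, dirty ends, truncated homology). A
small cache-resident presence bitmap rejects seed probes from unrelated
sequence before they touch the main index, which makes cross-species
comparisons — almost all of which find nothing — cheap.

One-way ANI is the unweighted mean identity over accepted fragments
(unweighted because trailing fragments differ in length and the
fragment-ANI convention averages per-fragment identities), and coverage is
the aligned query length divided by the total query length. A pair is
redundant only if **both** directions pass **both** thresholds:
ANI at or above `theta = 99`% and coverage at or above `gamma = 75`% —
requiring the comparison to hold from each genome's perspective prevents a
small, complete subset of a larger genome from absorbing it.

## Grouping and representative selection

Passing pairs form redundancy groups within each pre-cluster. The default
takes connected components of the pass graph — the weakest defensible
reading of "pairs above the threshold are dereplicated", and the one that
exposes chaining behaviour honestly. A stricter `grouping = "complete"`
builds groups in which every pair passes, grown greedily from the
highest-quality seed genome. Each group keeps the genome maximising
`completeness - w x contamination` with `w = 5`, the usual operational
form of "highest completeness, lowest contamination" (the two-objective
rule needs a trade-off weight; `w = 0` recovers pure-completeness
selection). Ties break by genome length, then id, so runs are
deterministic. Representatives are chosen after grouping; choosing before
grouping would only matter under `complete` grouping, where the greedy
seed is, by construction, the would-be representative anyway.

## The synthetic genome generator

Every claim above is testable without downloads because the package ships
a generator with known ground truth. It plants `n_species` ancestors
(independent random sequences below 90% between-species ANI; siblings
diverged from a common root above it, so species-boundary regimes near
95–96.5% are constructible), evolves each MAG from its species ancestor
with i.i.d. substitutions and geometric-length indels, inserts
genome-specific auxiliary segments (registered as planted pangenome gene
clusters, each carried by a random non-empty subset of the species' MAGs),
fragments each MAG into contigs at random breakpoints, and optionally
subsamples contigs to a drawn completeness. `within_ani` and `between_ani`
are *pairwise* targets: each branch carries half the divergence, so the
defaults (99.5% within, 80% between) put conspecific pairs safely above
and cross-species pairs far below the 99% decision threshold. The quality
table carries the true completeness with 0.5-point Gaussian estimation
noise and zero contamination.

Defaults describe a modest bacterial MAG: 200-kb genomes (large enough for
stable ANI and sketch statistics at desk scale), 20 contigs, indel rate
5e-4 per base with mean length 3, five auxiliary clusters of 2 kb per
species. What the generator does **not** emulate: sequencing and assembly
error, strain-level rearrangements and inversions, composition bias (GC
skew, repeats), contamination (chimeric bins), or realistic contig-length
distributions. Passing tests therefore demonstrate that the method's
logic and statistics behave as designed — not that real MAG catalogues,
with their messier error structure, will match any particular number.

## Evaluation procedures

Three procedures probe the method's operating characteristics:

* **Completeness subsampling.** Genomes are reduced to a target
  completeness by retaining a shuffled prefix of contigs whose cumulative
  length fits the target (never fewer than one contig), and the pipeline
  is re-run over a completeness-by-coverage-threshold grid. Because a
  genome subsampled to fraction `f` covers its partner at about
  `f x 100`%, coverage thresholds above that level block dereplication of
  incomplete conspecifics entirely — retained counts jump to the full set
  size once completeness falls below the coverage threshold, and lowering
  the threshold restores collapse. ANI results are computed once per
  subsampled set and re-thresholded per coverage value (the decisions, not
  the alignments, depend on the threshold).
* **Gene-cluster retention.** Given a genome-to-gene-cluster membership
  table, retention counts the clusters with at least one retained carrier;
  `retained + lost = universe` by construction.
* **Coverage dilution.** Reads drawn uniformly from a source genome are
  assigned to the database genome(s) containing their best match
  (exact-substring search on both strands, with the fragment aligner as a
  fallback for inexact cases), ties broken uniformly at random — the
  "one random alignment reported" behaviour of common mappers; an
  `report_all` mode credits every tied genome instead. With four identical
  database genomes each copy receives about a quarter of the reads; after
  dereplication the single representative receives them all.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; output labels are 1-based.
* Sketch hashes are compared as fixed-width hexadecimal strings, which
  order identically to their 64-bit values and survive TSV round-trips
  exactly.
* Tied merge heights can differ by floating jitter; spreads below
  `1e-10 x height` are treated as zero in the inconsistency coefficient.
* A pair with no accepted fragments has undefined ANI and is never
  redundant; a genome yielding zero fragments is an error, not a silent
  skip.
* Single-genome inputs pass through as one singleton cluster; duplicate
  genome files collapse (distance 0, ANI 100).
* All randomness (generator, subsampling, read placement, tie-breaks) goes
  through explicit integer seeds; the dereplication pipeline itself is
  deterministic, which is what makes byte-identical reruns testable.

## Problem sizes in the test-suite

The suite exercises the study conditions at desk scale: 200-kb genomes for
ANI recovery (divergences 0.5%, 1%, 3.5%, five seeds each), one hundred
100-kb genome pairs for sketch fidelity, twenty seeded trials of the
4-species x 5-MAG recovery experiment, a 10-MAG single-species set for the
completeness grid at fractions {0.4, 0.7, 1.0} and coverage thresholds
{25, 75}, and 4000 simulated reads for the dilution experiment. Smaller
(60-kb, 2 x 3) sets back the unit tests.

## Known limitations

* Seeding with exact 15-mers bounds the detectable divergence: below
  roughly 75% identity fragments rarely carry enough seeds, so reported
  ANI for very distant pairs is based on few fragments or undefined. This
  is irrelevant to dereplication decisions near 99% but makes the tool the
  wrong instrument for distant taxonomy.
* The banded alignment caps the net indel offset per fragment at 10% of
  the fragment length on each side; fragments spanning larger structural
  differences lose their hit and show up as reduced coverage instead.
* Pre-clustering with the default inconsistency criterion can leave
  well-separated groups in one pre-cluster (see above); this costs compute,
  never correctness.
* Quality estimates are inputs, not outputs: the package deliberately does
  not estimate completeness or contamination.
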