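---
title: "Detecting repeat-mediated recombination in plant mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting repeat-mediated recombination in plant mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorecomb)
```

## The biological problem

Vascular plant mitochondrial genomes are large (hundreds of kb to several
Mb), mostly intergenic spacer, and structurally fluid. The assembled
"master" molecule coexists *in vivo* with rearranged alternative
conformations at substoichiometric levels, produced by homologous
recombination between repeated sequences: recombination between **inverted**
repeat copies inverts the segment between them, while recombination between
**direct** repeat copies excises the intervening segment into a sub-circle.
Long sequencing reads can witness these events directly: a read that crosses
a repeat and runs into the "wrong" flank on the far side must come from a
recombinant molecule.

`mitorecomb` implements this analysis as a reusable pipeline:

1. **repeat census** — find all repeated pairs ≥ 50 bp at > 85% identity and
   classify them as small (< 100 bp), medium (100–1000 bp) or large
   (> 1000 bp);
2. **conformation references** — for each repeat pair, build flanked
   reference sequences for the master and recombinant arrangements;
3. **read support** — count long reads whose alignments distinguish master
   from alternative conformations, and flag recombinationally active
   repeats;
4. **gene-order comparison** — DCJ rearrangement distances and conserved
   gene clusters across organisms;
5. **homology annotation** — plastid-derived segments in spacers,
   inter-genome spacer sharing, and concatenated-alignment statistics;
6. **synthetic data** — a seeded generator producing genomes with planted
   repeats, recombinant conformations, and long reads with complete ground
   truth, used throughout the test suite.

## Conformation references

For a repeat pair with copies $R_1$ (flanks $A$ upstream, $B$ downstream)
and $R_2$ (flanks $C$, $D$), each flank 1000 bp, the master references are
the genomic arrangements $A\,R_1\,B$ and $C\,R_2\,D$. Recombination
exchanges flanks across the repeat. When the copies are identical there is a
single repeat sequence $R$ and two distinct recombinants
($A\,R\,D$ and $C\,R\,B$ for a direct pair), four references in all. When
the copies differ, each junction product can carry either repeat version and
the repeat can also be swapped between its native flanks, giving six
recombinants and eight references. For inverted pairs the exchanged flanks
enter reverse-complemented ($A\,R_1\,\overline{C}$ and
$\overline{B}\,R_2\,D$), so that every reference is a contiguous plausible
molecule; these junctions are exactly the ones produced by inverting the
genomic segment between (and including) the copies, and the test suite
verifies that identity against the explicit inversion product.

Recombinants that are themselves present in the genome carry no
recombination evidence (reads matching them may come from the master
molecule), so they are screened out before counting. The screen removes an
alternative reference when a single genomic alignment covers ≥ 95% of its
length at ≥ 95% identity and spans its recombinant junctions. The thresholds
are a design choice exposed in `pipeline_config()`; the degenerate inputs
that make the screen necessary are period-shifted copy pairs inside long
tandem arrays, where the "recombinant" is an exact genomic substring.

A read supports a reference when a **single** local alignment (either
strand) has > 95% identity and covers at least 200 bp of both repeat flanks.
Multiple disjoint alignments are never chained — a stricter rule than
chaining, chosen because a chained pair of flank hits cannot distinguish
conformations when the repeat is longer than the read. Each read votes for
at most one reference per repeat pair: its best-scoring qualifying
alignment, ties broken toward the master role so the "active" call stays
conservative. A repeat is recombinationally active when at least one read
supports an alternative conformation. Support percentages are rounded
half-up to two decimals, matching the convention of printed recombination
frequency tables.

## The repeat scan

The census is a genome self-comparison. The engine seeds candidate
diagonals with shared 12-mers (genome vs itself for direct repeats, genome
vs its reverse complement for inverted ones), merges seed runs, extends them
without gaps under a +1 match / −4 mismatch score with an X-drop of 40, and
trims each hit to its maximal-scoring segment (all maximal segments on a
diagonal are recovered Ruzzo–Tompa style, since ends always land on
matches). With penalty 4 a segment is extended only while its local identity
stays above 80%, so the reported pairs satisfy the > 85% identity filter
with a margin, and an **exact** repeat is reported at exactly its maximal
exact boundaries — the property that lets the test suite demand strict
equality with a brute-force all-diagonals oracle. `N` and ambiguity bases
never count as matches. Identity is matches divided by alignment columns,
reported to two decimals.

Two limitations are deliberate. First, extension is ungapped: repeat copies
that differ by insertions or deletions fragment into per-diagonal pieces.
The synthetic generator degrades copies by substitutions only, so the
pipeline's validated domain is substitution-diverged repeats; scanning real
genomes with indel-diverged copies would need a gapped engine behind the
same interface. Second, k-mer seeding loses sensitivity near the identity
floor: a 50-bp copy at 86% identity contains a 12-mer exact match only with
moderate probability. Both trade-offs favour exactness and auditability on
the scales the package validates.

A scanned repeat can extend a few bases past its planted boundary when the
adjacent background happens to align profitably (a chance run of matching
bases just outside the copy). Truth matching in `evaluate_recovery()`
therefore allows a configurable boundary wobble (default 10 bp); estimated
mixture fractions are unaffected.

## The synthetic-data generator

`generate_genome()` draws an i.i.d. background (uniform ACGT by default; a
GC knob reproduces, e.g., the ~46.6% GC typical of angiosperm mitochondrial
genomes) and plants each repeat by copying a source segment and degrading
the copy to the target identity with uniformly placed substitutions,
reverse-complementing it for inverted specs. Three refinements keep the
ground truth exact:

* substitutions avoid the first and last base of the copy, so the planted
  coordinates are not trimmed away by alignment;
* the bases immediately outside each copy are forced to disagree, so the
  planted coordinates are the maximal repeat coordinates;
* the two copies of a direct repeat are kept at least `min_separation`
  (default 25 kb, or a quarter of the genome) apart on **both** arcs, so
  that recombination sub-circles stay long enough to draw long reads from —
  mirroring the fact that real recombining direct repeats partition the
  genome into large sub-circles.

`apply_recombination()` produces the rearranged molecules (inversion for
inverted pairs; two sub-circles for direct pairs on a circle; a deletion
circle plus linear remainder for direct pairs on a linear molecule), and
`conformation_mixture()` assembles a molecule pool in which a chosen
fraction of molecules carry the recombinant arrangement, weighting the
products of a direct-repeat split by length so read coverage per bp is
uniform across the alternative pool.

`simulate_reads()` draws each read's source conformation from the mixture
weights, a uniform start (wrapping on circular molecules), a lognormal
length (default mean 15 kb, sdlog 0.5 — long-read studies report means of
order 10–25 kb and rarely more about the distribution), a uniform strand,
and i.i.d. errors at a configurable rate split
substitution:insertion:deletion = 2:1:1. The error model is deliberately
simple — it exercises the 95% identity threshold without modelling
platform-specific artefacts such as homopolymer errors, which matters
little here because the analysis protocol assumes error-corrected reads.
Every read carries a truth record (source molecule, start, strand, length,
error positions), and identical seeds reproduce byte-identical outputs.

Note that several repeats cannot be planted at an alternative fraction of
0.5 *simultaneously*: with single-event molecules, each repeat's fraction
equals its own molecules' weight, and the weights must sum to 1. Recovery
experiments therefore plant one active repeat per mixture and iterate over
repeats; multi-event molecules are out of scope.

What passing tests do show: on substitution-diverged planted repeats with
error-free or low-error reads, the pipeline recovers repeat coordinates,
the 4/8 conformation-count law, and planted mixture fractions within
binomial error. What they do not show: performance on indel-diverged
repeats, chimeric or systematically biased reads, or coverage
non-uniformity — real-data effects outside the generator's scope.

## Gene-order comparison

Signed, possibly multichromosomal gene orders are read from a simple text
dialect (`>` organism lines; whitespace-separated signed gene tokens; a
chromosome ending in `)` is circular; each chromosome occupies one line).
The DCJ (double-cut-and-join) distance between two genomes over the same
single-copy gene set is computed from the adjacency graph as
$d = N - (C + I/2)$, with $N$ genes, $C$ cycles, and $I$ odd paths. The
implementation is validated against breadth-first search over actual DCJ
operations on all adjacency states for small $N$ — an oracle that is
exhaustive rather than formula-based. Because compared genomes differ in
gene content, `reduce_to_shared_genes()` first restricts both orders to
genes present exactly once in each, reporting what it dropped; trans-spliced
gene fragments listed as separate tokens are treated as distinct markers,
not merged. The unrestricted DCJ model is the only one implemented — it is
the default model of the standard gene-order comparison tools, but printed
rearrangement counts from other models need not match it exactly.

Conserved clusters are maximal runs of shared single-copy genes that occur
contiguously, with consistent relative orientation, in every organism; a
run and its signed reversal are one cluster, circular chromosomes are
scanned across the origin, and reported clusters cannot be extended by one
gene without breaking conservation in some organism.

## Homology annotation and matrix statistics

Plastid-derived segments are annotated by a blastn search of the
mitochondrial genome (or its spacers) against a plastome at an e-value
cutoff of 1e-6, with hits overlapping on the query merged into disjoint
maximal segments — the convention of plastid-insertion tables, which list
disjoint insertions. A merged segment reports its best constituent hit's
identity and the subject genes its hits overlap, suffixed "(partial)" for
any gene not fully covered. Spacer sharing between genomes is the union of
segment intervals intersected with the spacer set.

For concatenated phylogenomic matrices, a column is parsimony-informative
when at least two distinct states each occur in at least two taxa; gaps,
`?`, `N`/`X` and IUPAC ambiguity codes count as missing, never as states —
the conventional definition. `concat_alignments()` fills taxa absent from a
gene with the missing symbol and records each gene's column range.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere.
* All external searches (read support, recombinant screening, homology
  annotation, mitochondrial-read extraction) go through one blastn wrapper
  (`blast_hits()`); the rest of the package depends only on its tabular
  contract, so the engine is replaceable. Low-complexity masking is off by
  default: organellar queries are small and masking costs sensitivity on
  AT-rich spacers.
* The repeat scan itself is native R (seeded diagonals, exact scoring), not
  blastn: exact-boundary reporting for identical copies is a correctness
  requirement of the census that a gapped X-drop engine does not guarantee.
* Percentages print half-up at two decimals; `round_half_up()` is exported
  because base R rounds half to even.
* Flanks wrap around the origin on circular genomes; on linear genomes they
  truncate with a warning, and conformation building refuses flanks shorter
  than the 200-bp read-support window.
* Ties in read assignment go to the master role, then the lowest reference
  index, making the recombination call conservative and deterministic.

## Problem sizes

The validation suite runs on synthetic genomes of 4–100 kb with planted
repeats of 80 bp–5 kb, read sets of 400–10,000 reads, exhaustive DCJ state
spaces up to $n = 6$ genes (10,395 adjacency states), and 100 random
alignments of up to 20 taxa × 200 columns. These sizes keep every oracle
exhaustive or exactly enumerable while exercising the same code paths a
~1-Mb genome with a ~174,000-read database would use; the genome-scale
figures of published studies additionally depend on sequence downloads and
engine-level settings that are outside the desk-scale validation surface.
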