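# mitorecomb

Repeat-mediated recombination analysis for plant mitochondrial genomes.

Vascular plant mitochondrial genomes are structurally fluid: alongside the
assembled "master" molecule, rearranged **alternative conformations** exist
at substoichiometric levels, produced by homologous recombination between
repeated sequences. Recombination between inverted repeat copies inverts
the intervening segment; recombination between direct copies excises a
sub-circle. Long reads witness these events directly — a read that crosses
a repeat copy and continues into the *other* copy's flank must come from a
recombinant molecule.

`mitorecomb` is for researchers analysing organellar genome structure from
long-read data. It provides:

* **Repeat census** — all repeated pairs ≥ 50 bp at > 85% identity, on
  either strand, classified small/medium/large (< 100 / 100–1000 /
  > 1000 bp);
* **Conformation references** — for a repeat pair with copies `R1` (flanks
  `A`, `B`) and `R2` (flanks `C`, `D`), the masters `A-R1-B` and `C-R2-D`
  plus the recombinant junction products (2 recombinants when the copies
  are identical, 6 when they differ → 4 or 8 references), with 1000-bp
  flanks and reverse-complemented flank exchange for inverted pairs;
* **Read-support counting** — a read supports a reference when one local
  alignment has > 95% identity and covers ≥ 200 bp of both repeat flanks;
  each read votes once per repeat pair (best alignment, ties to master); a
  repeat is *recombinationally active* when ≥ 1 read supports an
  alternative conformation;
* **Gene-order comparison** — DCJ rearrangement distance
  `d = N − (C + I/2)` from the adjacency graph, and conserved gene clusters
  shared across organisms;
* **Homology annotation** — plastid-derived segments in intergenic spacers
  (merged disjoint segments with carried genes), spacer sharing between
  genomes, and supermatrix statistics (missing data,
  parsimony-informative sites);
* **Synthetic data** — a seeded generator for genomes with planted repeats,
  recombinant conformations, and long reads from weighted conformation
  mixtures, with complete ground truth.

File formats: FASTA/FASTQ (Biostrings), GenBank flat files (feature table),
a signed gene-order text dialect, TSV outputs. Local alignment searches run
through NCBI BLAST+ (`blastn` on the PATH).

## Worked example

Generate a 100-kb circular genome with three planted repeats, scan it, and
measure read support for the largest repeat when half the molecules carry
its recombinant arrangement:

```r
library(mitorecomb)

gg <- generate_genome(100000, list(
  repeat_spec(5000, 100,  "direct"),
  repeat_spec(2000, 99.5, "inverted"),
  repeat_spec(300,  100,  "direct")
), seed = 1)

pairs <- find_repeat_pairs(gg$genome)
pairs
#> # A tibble: 3 x 11
#>      id length identity start1  end1 start2  end2 orientation size_class
#> 1     1   5000    100     1657  6656  37300 42299 direct      large
#> 2     2   2000     99.5  16760 18759  70207 72206 inverted    large
#> 3     3    300    100    29578 29877  91402 91701 direct      medium

repeat_summary(pairs, gg$genome)$gross_bp
#> 14600   # 14.6% of the genome covered by at least one repeat copy

mix <- conformation_mixture(gg$genome, pairs[1, ], alt_fraction = 0.5)
sim <- simulate_reads(mix$conformations, mix$weights, 400,
                      mean_len = 15000, error_rate = 0, seed = 2,
                      pair_ids = mix$pair_ids, genome_truth = gg$truth)
recombination_table(pairs[1, ], gg$genome, sim$reads)
#>   pair_id length identity orientation reads_alternative reads_master
#> 1       1   5000      100      direct                37           45
#>   alt_percent active
#> 1       45.12   TRUE
```

All three planted repeats are recovered at their exact coordinates. Of the
400 simulated reads, 82 span the largest repeat with ≥ 200 bp of both
flanks at > 95% identity; 37 of them (45.12%) support the recombinant
junctions — within binomial sampling error of the planted 50% mixture, and
the repeat is flagged active. With reads simulated from the master molecule
only, every repeat reports 0 alternative-supporting reads.

Gene-order comparison works from a simple signed dialect (`)` marks a
circular chromosome):

```r
orders <- load_gene_orders(text = c(">A", "rpl2 rps19 rps3 rpl16 nad3 rps12 )",
                                    ">B", "rpl2 rps19 rps3 rpl16 -rps12 -nad3 )"))
dcj_distance(orders[[1]], orders[[2]])
#> [1] 1
find_conserved_clusters(orders)$genes
#> [[1]]
#> [1] "rpl2"  "rps19" "rps3"  "rpl16"  (plus the nad3-rps12 block)
```

A thin command-line wrapper with `simulate` / `repeats` / `recomb` /
`matstats` subcommands is installed under `inst/scripts/mitorecomb-cli.R`.

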