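# annoquant

**annoquant** is a desk-scale R toolkit for a deceptively simple question in
RNA-seq analysis: *if you pick a different gene annotation (RefGene-like,
Ensembl-like, UCSC-like gene models), how much do your read mappings and
gene-level counts change — and why?* It is aimed at bioinformaticians who
want to study, teach, or regression-test the mechanics behind
annotation-dependent quantification, on fully synthetic data with known
ground truth, without downloading a reference genome or running a production
aligner.

## What it implements

* **Gene-model data structures and I/O** — genes → transcripts → exons with
  1-based inclusive GTF coordinates; strict GTF parser/writer, FASTA I/O,
  spliced transcript sequence extraction, and exact transcript↔genome
  coordinate projection (the block structure of junction reads).
* **A toy deterministic read mapper** with the three classic modes:
  *transcriptome only* (map to spliced transcripts, project hits back to the
  genome, collapse isoform duplicates), *genome only* (contiguous
  k-mismatch placements plus de-novo two-segment splice search), and
  *transcriptome + genome* (transcriptome first, genome as fallback).
  Per read it reports **#ML**, the number of best mapping locations:
  0 = unmapped, 1 = unique, ≥2 = multiple. Substitution-only model (no
  indels, no clipping), exhaustively enumerable — the test suite checks it
  against a brute-force oracle.
* **The two-stage protocol**: stage 1 filters out reads not covered by the
  model; stage 2 remaps the survivors with and without the model and
  classifies every uniquely mapped read as **Identical / Alternative /
  Multiple / Unmapped**, stratified by junction status.
* **Ambiguity-aware gene counting**: a unique alignment compatible with
  genes `G` adds 1 to a single compatible gene; if several genes are
  compatible, genes owning at least one read-length window unique to them
  split the read, otherwise all of `G` do. This reproduces the two classic
  case studies: a gene fully nested in another (no unique region) counts 0
  while the container takes everything; two genes sharing one identical
  bicistronic transcript split every read 50/50.
* **Concordance statistics**: per-gene ratio
  `max(c1+1, c2+1) / min(c1+1, c2+1)` (pseudocount +1, always ≥ 1), the
  NoExpr / Same / cumulative-threshold table at thresholds
  {1.05, 1.10, 1.20, 1.50, 2, 5, 10, 100}, `log2((c1+1)/(c2+1))` fold
  changes, and counts of genes whose two fold changes differ by > 1, 2, 5.
* **A synthetic-data generator**: random genomes, paired annotations that
  differ by six archetypes (identical; 3'-extension; nested gene vs shared
  identical transcript; absent/patch chromosome; model-unique gene;
  processed retro-copy written back into the genome), and uniform-coverage
  read simulation with per-read ground truth (origin blocks, junction flag,
  injected error positions).

## Worked example

```r
library(annoquant)

genome <- generate_genome(c(chr1 = 150000, chr2 = 150000), seed = 1)
world  <- generate_annotation_pair(genome, default_archetype_panel(), seed = 1)
sim    <- simulate_reads(world$genome, world$model_a, n_reads = 2000,
                         read_length = 75, error_rate = 0.001, seed = 1)

# two-stage protocol under the richer model A
st1     <- stage1_filter(sim$reads, world$model_a, world$genome)
without <- map_reads(st1$reads, "none", genome = world$genome)
stratified_summary(classify_reads(st1$batch, without))
#> junction fraction: 0.3183 (616 junction / 1319 non-junction)
#>              identical alternative multiple unmapped
#> junction         40.42       13.15    45.62     0.81
#> non_junction    100.00        0.00     0.00     0.00
```

Non-junction reads re-map identically without the model; junction reads are
the ones the gene model rescues — they come back spliced only if both
segments clear the anchor length, and the retro-copy archetype makes many of
them multiple. Now quantify under both models and compare:

```r
counts_a <- count_reads(st1$batch, world$model_a, 75)
b_b      <- map_reads(sim$reads, "transcriptome_only", world$model_b, world$genome)
counts_b <- count_reads(b_b, world$model_b, 75)
concordance_table(counts_a, counts_b)
#>   no_expr  same ge_1.05 ge_1.1 ge_1.2 ge_1.5  ge_2  ge_5 ge_10 ge_100
#> 1       0 73.68   26.32  26.32  26.32  26.32 21.05 21.05 15.79   5.26
```

74% of the 19 common genes count identically; the rest are exactly the
planted archetypes:

| gene | archetype | model A | model B | mechanism |
|------|-----------|--------:|--------:|-----------|
| G15  | 3' extension          | 139 | 26 | reads from the extended exon only map in A |
| G16  | nested pair container | 52  | 26 | A: container takes all shared reads |
| G16N | nested gene           | 0   | 26 | A: no unique region → 0; B: 50/50 split |
| G17  | absent chromosome     | 406 | 0  | B puts it on a patch chromosome missing from the genome |
| G19  | retro-copy source     | 0   | 65 | A annotates the retro-copy too → reads go multiple and are discarded |

Run the same thing as one call (writes GTF/FASTA/FASTQ/SAM/TSV/JSON bundle):

```r
run_pipeline(pipeline_config(out_dir = "out", seed = 1))
```

or from the shell via the bundled CLI:

```sh
Rscript inst/cli/annoquant run --out-dir out --seed 1
```

## Documentation

The methods vignette (`vignettes/annotation-impact.Rmd`) describes the
mapping model and its assumptions, the counting rules, what the synthetic
generator does and does not emulate, and the numerical conventions
(rounding, tie-breaks, pseudocounts).
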