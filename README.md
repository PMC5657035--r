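# gtasm — gene-targeted metagenomic assembly with HMM-guided graph search

`gtasm` assembles contigs of a *specific gene family* — phylogenetic
markers like rplB, functional markers like nifH or nirK — directly from
shotgun metagenomic reads, instead of hoping a de novo assembler recovers
them intact. It is aimed at microbiome researchers who have (i) reads,
(ii) an aligned panel of reference sequences for the family, and
optionally (iii) a HMMER3 profile HMM, and who want full-length gene
contigs with reproducible, inspectable scoring.

## The method

Three ideas work together:

1. **Combined weighted assembly graph.** The de Bruijn graph *D* of the
   reads (vertices = k-mers, edges = (k−1)-overlaps, stored exactly with
   per-k-mer multiplicities) is crossed with a profile HMM *H* of the gene
   family (match/insert/delete states per alignment column). In the
   product graph a path simultaneously spells a read-supported sequence
   and an alignment to the model. Edges into a match state weigh
   `ln P_transition + ln P_emission(j, c)` (c = last character of the new
   k-mer); edges into insert or delete states weigh `ln P_transition`
   only. The best start-to-end path is found exactly by A* under an
   admissible HMM-only heuristic; starting vertices are read k-mers that
   exactly match windows of the reference alignment, extended both ways
   (a reversed model guides the leftward search) and merged.

2. **Low-coverage penalty.** Every edge entering a k-mer seen exactly once
   in the reads receives an additive `ln(alpha)`, `alpha = 0.5` by
   default — a prior that count-1 k-mers are sequencing errors. `alpha = 1`
   disables the penalty bit-exactly.

3. **Iterative multi-k graphs.** With `G(k1) = DBG(R, k1)`,
   `C(ki)` = cleaned unitigs of `G(ki)`, and
   `G(ki+1) = DBG(R ∪ C(ki), ki+1)`, contigs assembled at a small k carry
   connectivity across thin-coverage regions into the specific large-k
   graph (defaults k = 30, 36, 45).

Post-processing filters contigs at 450 nt / 150 aa and clusters them
greedily longest-first at 99% identity, keeping each cluster's longest
member. A built-in simulator (`simulate_family()`) generates gene
families, coverage profiles with gaps, substitution errors and background
reads for offline validation, and `recovery_report()` scores contigs
against the simulated truth.

## Worked example

Simulate a 300-nt gene sequenced at depth 25 with 0.2% substitution
errors, assemble it with the iterative plan k = 21, 41, and evaluate
against the simulated truth:

```r
library(gtasm)

sim <- simulate_family(sim_config(
  seed = 5, gene_length = 300, n_family_members = 1,
  read_length = 50, substitution_error_rate = 0.002,
  coverage = list(type = "flat", depth = 25), background_reads = 10))

refs <- setNames(rep(sim$alignment, 2), c("ref1", "ref2"))
res <- run_pipeline(sim$reads, refs, out_dir = "demo_out",
                    k_list = c(21, 41), alpha = 0.5,
                    min_nt = 150, max_seeds = 10)
#> building iterative de Bruijn graph, k = 21,41
#> final graph: 972 k-mers at k = 41
#> 256 seeds; searching (alpha = 0.5)
#> 1 raw contigs
#> 1 representative contigs after post-processing

rep <- recovery_report(vapply(res$contigs, `[[`, "", "sequence"), sim$genes)
rep$per_gene
#>       gene length covered fraction
#> 1 member01    300     296 98.66667
rep$mismatches_per_100kbp
#> [1] 0
```

The log lines say what happened: a 972-k-mer double-stranded graph at the
final k = 41, 256 seed k-mers matching the reference alignment (all but
the first skipped by dereplication once its contig covers them), one raw
contig, one cluster representative. The report shows the planted gene
recovered over 296 of its 300 bases (98.7% — read sampling tapers at the
gene termini) with zero mismatched bases per 100 kbp of aligned contig.
`demo_out/` holds the contig FASTA files, the cluster and seed-report
tables, and `config.yaml` with every parameter that affected the run.

The same pipeline runs from a shell via the thin wrapper:

```sh
Rscript inst/scripts/gtasm.R run --reads reads.fastq.gz \
    --refs refs.aln.fasta --out outdir --k-list 30,36,45 --alpha 0.5
```

Two packaged experiments reproduce the method's two comparative claims at
desk scale: `compare_k_strategies(seed)` (iterative [21, 41] vs single
k = 41 on gap-coverage simulations, reporting recovered gene fraction) and
`compare_penalty(seed)` (`alpha = 0.5` vs `alpha = 1` on error-injected
simulations, reporting mismatches per 100 kbp).

## Scope

`gtasm` implements the full method in R with an exact hash-based graph
store; it is built for method study and moderate gene-targeted problems,
not for billion-read soil metagenomes — succinct graph encodings, Bloom
filters, paired-end logic and external chimera-removal tools are
deliberately out of scope (the cluster table and representative FASTA are
formatted to feed such tools downstream).
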