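---
title: "HMM-guided gene-targeted assembly: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HMM-guided gene-targeted assembly: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtasm)
```

## The problem

Shotgun metagenomes mix reads from hundreds of genomes at wildly uneven
coverage. De novo assemblers stop at every ambiguous branch, so
single-copy marker genes (rplB) and functional markers (nifH, nirK) come
out fragmented. Gene-targeted assembly turns the problem around: given a
profile hidden Markov model of the gene family of interest and a panel of
aligned reference sequences, it searches the de Bruijn graph of the reads
for the paths that the model considers most probable, and reports those
paths as gene contigs.

## The combined weighted assembly graph

Two structures are combined:

* a **de Bruijn graph** D over the reads: vertices are k-mers, and a
  directed edge joins u to v when the (k−1)-suffix of u equals the
  (k−1)-prefix of v. `gtasm` stores D as an exact hash map from k-mer to
  **multiplicity** (occurrence count). Exactness matters twice: a
  probabilistic membership structure can hallucinate k-mers into the middle
  of a contig, and the multiplicity is the error signal the search
  penalizes on.
* a **profile HMM** H of the family: per alignment column a match state
  (with an emission distribution over residues), an insert state and a
  delete state, with the usual 7-transition topology plus begin/end.

The **combined assembly graph** C is their product. A vertex w pairs a
k-mer `w.u` with an HMM node `w.v`. An edge (w, w′) exists when either

1. (w.u, w′.u) is an edge of D, (w.v, w′.v) an edge of H, and w′.v is a
   match or insert state — the path advances one character in the reads and
   one step in the model; or
2. w.u = w′.u and (w.v, w′.v) is an edge of H with w′.v a delete state —
   the model advances past a column the reads do not cover.

Edge weights are natural-log probabilities:

* into a match state: `ln P_transition + ln P_emission(j, c)` where c is
  the last character of w′.u;
* into an insert or delete state: `ln P_transition` only.

Insert emissions present in HMMER files are parsed but never scored; the
path weight assigns insert edges a transition term only, which diverges
from HMMER's own scoring semantics and is documented here deliberately.

A best path from a starting vertex to any vertex whose HMM component is
the end node simultaneously spells a sequence supported by the reads and
an alignment of that sequence to the model.

## The low-coverage penalty

A k-mer observed exactly once in the reads is, at usual coverage, more
likely a sequencing error than a real variant. Every CAG edge entering a
multiplicity-1 k-mer receives an additive `ln(alpha)` with
`alpha = 0.5` by default — equivalent to a prior probability of 0.5 that a
count-1 k-mer is wrong. `alpha = 1` disables the penalty exactly (the
scores are bit-identical to a penalty-free search). Delete edges consume no
new k-mer and are never penalized; the same reasoning exempts them in the
one open interpretive question we had to settle. The penalty changes branch
choice precisely when the erroneous branch's score advantage per penalized
k-mer is below `|ln alpha|` — the margin test in the acceptance suite
constructs both sides of that boundary.

K-mers that enter the final graph only via carried contigs of the
iterative construction (below) have multiplicity 1 by construction; the
`exempt_contig_kmers` flag of `penalty_config()` can exempt them. It is off
by default: a bridge supported by a single small-k contig is still
single-evidence.

## Iterative multi-k construction

Small k keeps low-coverage regions connected but collapses repeats and
multiplies branches; large k is specific but fragments thin coverage. The
iterative construction takes an increasing k list (default 30, 36, 45; the
desk-scale experiments use 21/41 scaled to 50-nt reads):

```
G(k1) = DBG(reads, k1)
C(ki) = cleaned unitigs of G(ki)
G(ki+1) = DBG(reads ∪ C(ki), ki+1)
```

Contigs assembled at a smaller k contribute the large-k k-mers that thin
coverage failed to produce directly. Carried contigs are always plain
unitigs — never HMM-guided products, whose small-k errors would accumulate
into the final graph. K-mers contributed only by carried contigs count
once plus their read support (a simple sum); the final graph records which
k-mers have no direct read support at the final k.

Each intermediate graph is cleaned (tips, then bubbles, iterated to a
fixpoint, at most 10 rounds) before its unitigs are spelled, and the final
graph is cleaned too before search (`final_clean = FALSE` opts out). The
cleaning thresholds are package choices, not literature values: tips up to
2k k-mers are removed when their mean multiplicity is below the strongest
competing branch's; bubble arms up to 3k characters whose spelled lengths
differ by at most 3 are merged by deleting the lower-multiplicity arm. Ties
delete the lexicographically larger spelled path, so cleaning is
deterministic. At most one graph is alive at a time.

## Seeds and bidirectional search

A **seed** is a k-mer that occurs in the reads and exactly matches a
degapped window of the reference alignment. The window's last character's
alignment column gives the anchoring match position; windows ending in
insert columns anchor to the nearest preceding match column, and windows
entirely inside insert regions are skipped.

From each seed the search runs twice: forward under the model, and
leftward under the **reversed model** working through predecessor k-mers.
The reversed model mirrors the emission columns and reverses every
transition edge; each reversed edge is weighted by the expected number of
times the original edge is traversed in a begin-to-end generative pass
(state-visit frequency × conditional transition probability), then
outgoing mass is renormalized per state. Weighting by traversal frequency
rather than raw conditional probability is what makes the reversal exact
on branch-free models — transitions out of never-visited states carry no
mass and cannot distort the reversed match chain. The contig is
(reversed leftward spelling) + seed + rightward spelling, with score the
sum of both directions.

Seeds whose k-mer already lies inside an emitted contig are skipped, and a
contig whose k-mer set is contained in an earlier one is dropped — seed
dereplication, applied before search so desk-scale runs stay fast without
changing the dereplicated output.

## A* search: heuristic, termination, ties

The search maximizes summed edge weight with A*. The heuristic is computed
once per model by backward dynamic programming over the HMM alone: from
(position, state), the best achievable remaining score ignoring the graph,
the penalty, and scoring every match step with its best-case emission.
Ignoring only score-decreasing constraints makes it an upper bound
(admissible) and consistent, so the first end-node vertex popped is the
global optimum and each (k-mer, position, state) vertex is expanded at
most once. That closed-set property also bounds insert runs — an insert
cycle would need a strictly improving revisit, which non-positive edge
weights forbid — so no separate insert-run cap is needed.

Ties in f-score pop with the higher g-score first, then the
lexicographically smaller k-mer: results are deterministic, and two runs of
the full pipeline are byte-identical.

If no terminating vertex is reachable (or `max_expansions`, default 10^6,
is exhausted) the best-scoring dead-end path is returned flagged
`partial = TRUE` — never silently truncated, never discarded unless both
directions are partial and the merged contig is shorter than k.

## Model building and numerical choices

`hmm_from_alignment()` follows the textbook construction: columns with gap
fraction strictly below 0.5 are match columns (a tie goes to insert — the
boundary must be fixed for determinism); transitions and emissions are
Laplace-smoothed relative frequencies. The function default pseudocount
is 1, but `run_pipeline()` builds models with pseudocount 0.1: with
add-one smoothing on a panel of two to ten references, match emissions
flatten toward 1/4 while unobserved delete-delete transitions sit at 1/2,
and an all-delete path through the model can outscore faithful matching.
A pseudocount of 0.1 keeps match steps competitive while still assigning
every event nonzero probability. Observed transitions outside the
7-transition topology (I→D, D→I, possible in unusual alignments) are
dropped, as in plan-7 model building.

HMMER3 ASCII files store negated natural logs with `*` for probability
zero; the reader converts and validates per-state normalization to 1e-4
(files are rounded to a few decimals), while in-memory constructors
validate to 1e-6. The writer emits 7 decimals so models round-trip.

Clustering identity (post-processing, threshold 0.99) is matches divided
by alignment columns of a global alignment with free end gaps, evaluated
over the shorter sequence — so a contig contained in a longer one scores
identity 1 and joins its cluster, and clustering at threshold 1.0 merges
exactly the (sub)sequence-identical contigs. Clustering is greedy
longest-first; the founder of each cluster is its representative. Length
filtering (450 nt / 150 aa, inclusive) runs first.

Both alphabets are supported end to end, but the model's alphabet must
equal the graph's: the codon-stepping trick of searching a nucleotide
graph with a protein model is out of scope, as the edge conditions here
are strictly one character per edge.

## What the simulator does and does not emulate

`simulate_family()` generates a family by mutating a random ancestor
(substitutions only, at half the target pairwise divergence), so the true
alignment is gap-free and model building from it is exact. Reads are
sampled from both strands under a flat, gradient, or gap coverage profile;
in the gap profile, randomly placed reads never overlap the gap and a
single deterministic tiling (stride 20, 50-nt reads, hence 30-nt overlaps)
crosses it — connected at k = 21, broken at k = 41 by construction.
Substitution errors are injected per base; background reads are uniform
random. One seed drives everything through fixed per-stage offsets, so
outputs are byte-reproducible and adding a stage never perturbs earlier
ones.

Not emulated: indels (and therefore gapped family alignments), quality
scores, paired ends, chimeric reads, real abundance profiles, and
composition bias. Passing tests on these fixtures show the algorithmic
contracts hold — exact graphs, optimal search, penalty and multi-k
behavior — not that recovery rates transfer quantitatively to real
metagenomes. Uniform read starts also taper coverage at gene termini, so
simulated gene fractions sit a little below 100 even at high depth.

## Desk-scale experiment sizes

The two packaged experiments are sized for a laptop: one 150–200-nt gene
family, 50-nt reads at depth 20, and 10 simulation seeds per comparison.
`compare_k_strategies()` contrasts the iterative plan [21, 41] with single
k = 41 on gap-coverage data and reports recovered gene fractions;
`compare_penalty()` contrasts `alpha = 0.5` with `alpha = 1` in a design
that isolates the penalty's mechanism: reads come from a *single* gene at
depth 20 with 1% substitution errors, while the model is built from a
reference panel holding that gene plus two relatives at 10% divergence. At
columns where the gene disagrees with the rest of the panel, an error that
happens to match the panel consensus scores better than the true base by
roughly ln(2.1/3.4) − ln(1.1/3.4) ≈ 0.65 — below |ln 0.5| ≈ 0.69 — and
lies on multiplicity-1 k-mers, so the penalty demotes exactly these
detours while leaving well-supported paths untouched. Sequencing one gene
(rather than a mixed family) removes inter-member mosaic mismatches,
which neither arm controls and which would otherwise dominate the
comparison. The penalty experiment searches the *unpruned* final graph:
tip and bubble cleaning removes most erroneous count-1 k-mers outright,
which is the penalty's own job here, and pruning first would mask the
effect being measured. Means across 10 seeds are compared; on a single
seed either arm can win by small margins.

## Known limitations

* Pure-R traversal: fine for the desk-scale fixtures the package ships
  with; graphs with 10^7+ k-mers need the succinct-structure engineering
  this package deliberately does not attempt.
* `recovery_report()` is a minimal reference-based evaluator (coverage,
  mismatch rate, a flank-realignment chimera check with a 1 kb breakpoint
  rule), not a full assembly-evaluation tool.
* Chimera removal against references and frameshift-aware nearest-reference
  matching are external post-processing steps; the cluster table and
  representative FASTA are formatted to feed them.
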