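---
title: "Merging de novo transcriptome assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging de novo transcriptome assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

De novo transcriptome assemblers occupy different algorithmic niches: a
de Bruijn assembler at k = 25 recovers low-abundance transcripts that an
information-theoretic assembler misses, while a longer k-mer favours highly
expressed, well-covered transcripts. No single assembler recovers the whole
transcript community, so a natural strategy is to assemble the same reads
several ways and merge the candidate assemblies into one non-redundant
catalogue. The merge must solve two problems at once: recognise when contigs
from different assemblies represent the same underlying transcript
(clustering), and decide which of the redundant copies to keep (selection).
`txmerge` implements both, plus the evaluation battery needed to say whether
the merged assembly is actually better than its inputs.

## The pipeline

`orthofuse()` runs four stages, all deterministic given the inputs and the
configuration:

1. **Pooling.** Assemblies are concatenated; every contig id becomes
   `label|id`, so the assembler of origin survives any round trip through
   FASTA or SAM.
2. **Orthogroup formation.** A similarity graph is built over the pooled
   contigs: nodes are contigs, and an edge joins two contigs whose canonical
   k-mer *max-containment* — `|K(a) ∩ K(b)| / min(|K(a)|, |K(b)|)` at
   k = 31 — is at least 0.1. Candidate pairs come from a shared-k-mer
   inverted index, so the all-vs-all comparison is never materialised. The
   graph is partitioned by Markov clustering (MCL) with inflation 4.
3. **Contig scoring.** Reads are aligned to the pooled set (bundled
   exact-seed mapper, or a user-supplied SAM), and every contig receives a
   composite read-evidence score (below).
4. **Selection.** The highest-scoring member of each orthogroup becomes its
   representative in the merged assembly. Ties go to the longer contig, then
   to the lexicographically smallest id. Singleton groups are always kept:
   an unclustered contig is unique content, not noise.

## Similarity: why containment, not Jaccard

Transcript pools mix full-length contigs with fragments. A half-length
fragment shares at most half its parent's k-mers, so its Jaccard similarity
is capped near 0.5 and falls fast with fragment size; its containment in the
parent is 1.0 regardless. Selection assumes fragments and parents co-cluster
(so the full-length copy can win), which containment guarantees and Jaccard
does not. The threshold 0.1 sits far below genuine homology signal at
k = 31 — unrelated random sequences essentially never share a 31-mer — while
pruning the quadratic pair space; it is exposed as a parameter.

## Clustering: MCL at inflation 4, with hub damping

MCL alternates expansion (matrix squaring of the column-stochastic adjacency
matrix, self-loops at each node's maximum incident weight) and inflation
(entrywise power followed by column renormalisation), pruning entries below
1e-5, until the largest entry changes by less than 1e-6. Attractors (nodes
with non-negligible self-mass in the limit) define clusters; a node attracted
to several systems goes to its highest-mass attractor, ties to the lowest
group id. Disconnected components can never merge under MCL, so the
iteration runs per component. The default inflation of 4 — twice MCL's
customary 2 — yields deliberately fine clusters so transcript isoforms
resist collapsing into a single group and can each field a representative.

One failure mode needs special treatment. A chimeric contig AB is, from the
k-mer perspective, indistinguishable from a parent of which A and B are
fragments: containment connects it at full strength to *both* source
orthogroups. On such a dumbbell, plain MCL makes the chimera the attractor
of everything it touches and glues the two groups into one (we verified this
on synthetic dumbbells: the chimera ends as the sole attractor). The package
therefore rescales each edge to `w / sqrt(s_i s_j)` (`s` = weighted node
degree) before clustering — a hub-damping normalisation in the spirit of
the score normalisation that orthology pipelines apply before MCL. A
chimera's weighted degree is roughly twice its neighbours', so precisely its
edges are weakened and the bridge is cut, while cliques and fragment–parent
stars keep their relative structure. `cluster_assemblies(normalize = FALSE)`
disables this; `markov_cluster()` itself is classic MCL, which is what the
test suite compares against an independent dense-matrix reference.

## Contig scoring

Four components, each in [0, 1], from primary alignments only:

* `s_nuc` — nucleotide fidelity: matched bases over aligned bases.
* `s_cov` — fraction of contig positions covered by at least one base.
* `s_ord` — pair agreement: among read pairs with *at least one* mate on
  the contig, the fraction whose mates are both on it, FR-oriented
  (leftmost mate forward) and within `insert_mean + 3·insert_sd`. Counting
  pairs whose other mate lands elsewhere is deliberate: those bridging
  pairs are the read-evidence signature of a fragmented transcript, and
  they are what lets selection prefer a full-length contig over a
  well-covered fragment of itself. With no pairs touching the contig the
  component is neutral (1.0), so short contigs are not annihilated by an
  undefined quantity.
* `s_seg` — single-transcript plausibility: a 1-segment versus best
  2-segment piecewise-constant model of `log2(coverage + 1)` under a
  Gaussian likelihood with shared variance, breakpoint searched on a decile
  grid over the middle 80% of positions. The score is the 1-segment model's
  BIC weight: near 1 for flat coverage (the 2-segment model pays its extra
  parameters), near 0 for the step profile of a chimera junction. Variance
  is floored at 1e-9 so zero-variance profiles stay finite; all-zero
  coverage scores 0 and flags the contig as unsupported.

The composite is the geometric mean of the four components after flooring
each at 0.01, so one catastrophic component dominates without zeroing the
product. The assembly-level score is the geometric mean of composites times
the mapping rate (fraction of pairs with both mates primary-mapped) — a
synthetic quality metric on the same [0, 1] scale that field tools report,
and the quantity the merge is meant to improve.

The chimera cluster {AB, A, B} deserves a note: selection keeps the
composite argmax, so if the false chimera AB outscored both parents it would
win and a real transcript would be lost from the catalogue. Coverage
segmentation is the guard: whenever A and B are expressed at different
levels, AB shows a coverage step and loses `s_seg`. When A and B happen to
be expressed identically the step vanishes and the guard is blind — a known
limitation of coverage-based chimera detection generally.

## The bundled mapper

A deliberately simple exact-seed, ungapped, substitution-only mapper for
benchmark-scale data: forward 31-mers of the contigs are indexed; each read
is tried in both orientations at several seed offsets; every seed hit
implies a diagonal placement scored by full-length mismatch count (up to 20%
of the read length). The best tier is kept; equal-best hits across contigs
are reported as secondary records so quantification can split multi-mapped
fragments. The primary among equal-best hits is chosen by a deterministic
hash of (read, contig) — a fixed pseudorandom choice. A lexicographic rule
here would be a systematic bias: with four near-identical copies of a
transcript in the pool, the alphabetically first label would absorb every
read and starve the others of evidence, making winner selection an artifact
of label names. Both mates of a pair share the hash key, so they stick to
the same copy. `tie_break = "id"` restores the strict lowest-id rule.

## Quantification and diagnostics

* `quantify()` counts fragments per contig (both mates on the contig at the
  best tier; multi-best-hit fragments split equally), normalises by
  effective length `max(length − insert_mean + 1, 1)` and scales to TPM. A
  fractional-count scheme, not an EM: its outputs are used ordinally (bias
  ridgelines, rank correlation with truth), where the simple estimator is
  sufficient and exactly reproducible.
* `sketch()` / `compare_sketches()` implement bottom-s MinHash (default
  s = 5000, k = 51) over canonical k-mers with a fixed 64-bit hash
  (FNV-1a + splitmix64 finalizer, top 53 bits so the values are exact in
  doubles). Distance is 1 minus the bottom-s merge estimate of Jaccard; at
  s = 5000 the sampling error is about 0.007, far inside the 0.05 the suite
  asserts.
* `mds_embed()` is classical (Torgerson) MDS via `stats::cmdscale`, with
  each axis's sign fixed so its largest-magnitude coordinate is positive.
  Classical rather than non-metric MDS is a deliberate divergence: the
  embedding is used qualitatively, and the closed-form solution is
  deterministic and exactly testable on Euclidean-realisable matrices.
* `duplication_report()` with a truth set reports the fraction of truth
  genes represented by more than one merged contig; without one, the
  fraction of merged contigs still similar to another merged contig at the
  clustering threshold (residual redundancy).

## The synthetic benchmark

`standard_benchmark()` generates the study conditions used throughout the
tests: 500 single-isoform genes (lengths log-normal, median 1.5 kb, floor
300 bp; expression log-normal with sdlog 1.5, normalised to TPM), 50,000
FR read pairs of 100 bp (the modal read length in public short-read RNA-seq)
with insert 250 ± 50 bp and 1% substitution error, and four corrupted
assemblies:

| profile  | dropout                                  | dup  | frag | chimera |
|----------|------------------------------------------|------|------|---------|
| trinity  | 13% expression-independent               | 0.18 | 0.06 | 0.04    |
| spades55 | logistic in log-TPM, midpoint 5th pctile | 0.06 | 0.05 | 0.04    |
| spades75 | midpoint 45th pctile, slope 1.6          | 0.06 | 0.05 | 0.04    |
| shannon  | midpoint 65th pctile, slope 2.5          | 0.03 | 0.03 | 0.02    |

Dropout is a logistic retention curve in log(TPM+1) rather than a hard
threshold, reproducing a smooth bias toward highly expressed transcripts;
midpoints sit at quantiles of the truth's expression so the profiles adapt
to each simulated transcriptome. The constants were chosen once so that the
qualitative structure the profiles emulate holds across seeds: per-assembly
gene recovery ordered shannon < spades75 < spades55 ≈ trinity, every single
assembly missing more than 10% of genes, and the union covering at least
95% — the complementarity that makes merging worthwhile in the first place.
Duplicates carry 0.5% substitutions, fragments split uniformly in the middle
half of the transcript, chimeras concatenate a retained transcript with
another random retained transcript, and all emitted contigs get 0.3%
substitution noise. Every contig is traceable to its source transcript(s)
through a provenance table; all generators are bit-reproducible under a
fixed seed.

What the generator does **not** emulate: indels (substitution-only errors
keep the mapper and fidelity score analytically checkable; an indel option
exists but defaults to 0), platform-specific error profiles, PCR
duplicates, strandedness, alternative splicing beyond block-shared
isoforms, and sequence repeats or paralogy. Passing tests on this benchmark
therefore show that the machinery behaves as designed under clean,
traceable corruption — not that merged assemblies of real reads will show
effects of the same magnitude.

## Evaluation choices

Cluster recovery is scored as the adjusted Rand index between orthogroups
and the true gene partition over *non-chimeric* contigs: a chimera spans two
genes and has no single true label, so including it under an arbitrary
first-source label would penalise the clustering for an assignment that is
undefined. Genuine bridge failures still count — both source cliques sit in
the erroneously merged group. On the standard benchmark the pipeline reaches
ARI ≈ 0.99; with chimeras force-labelled by their first source it is ≈ 0.94,
the gap being exactly the ambiguous contigs.

Problem sizes were chosen to make the full battery run comfortably on a
single core: 500 genes × 4 assemblies ≈ 2,200 pooled contigs and 50,000
pairs give each stage enough signal for the directional claims (mapping-rate
dominance, duplication reduction, expression-bias recovery) while a complete
merge runs in well under a minute.

## Known limitations

* Chimeras between equally expressed transcripts evade `s_seg` (no coverage
  step) and, if they win their group, cost a transcript.
* The mapper is ungapped and substitution-only; real indel-bearing reads
  need an external aligner (supply its SAM via `orthofuse(sam = ...)`).
* `quantify()` splits multi-mapped fragments equally rather than by EM; its
  TPMs are for ordinal use.
* Isoform handling is inherited from MCL granularity: inflation 4 resists
  isoform collapse but does not guarantee one group per isoform.
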