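---
title: "Core-genome phylogenomics with phylocore: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-genome phylogenomics with phylocore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phylocore reconstructs the comparative genomics of a bacterial clade from
per-genome annotation tables: a single-copy core-gene panel, a
concatenated core alignment, PNS-based species delimitation, gene-content
dissimilarity, pan/core rarefaction, core-genome synteny, and
Robinson-Foulds (RF) concordance between the trees those data layers
imply. This vignette explains the underlying models and procedures, the
parameters that matter, and the choices made where the design was
genuinely open. It states no empirical result that the package's tests do
not themselves compute.

## The analysis model

### Gene identity and the annotation matrix

Orthology is equated with the annotation *function string*: two calls are
copies of the same gene exactly when their function strings match. This
is the convention of annotation-table pipelines and is deliberately
simple; it is robust for well-behaved single-copy genes (the only ones
that survive the core filters) but cannot separate paralogs that share a
function string. Rows whose function is a *hypothetical protein*, *repeat
region* or *Mobile element protein* (case-insensitive; configurable) are
excluded from all abundance and copy-number statistics, since these
classes are annotation noise with respect to gene-content comparison.
Coding GC content is computed over the concatenated coding sequences of
**all** calls, including excluded classes — the exclusion list exists to
clean the gene-content universe, not the nucleotide composition.

### The core-gene panel

A gene is a **candidate** core gene when it occurs in exactly one copy in
at least 90% of genomes (`occupancy`, default 0.90, flip at exactly 90%).
Draft assemblies fragment genes across scaffolds and thereby fake both
duplications (two partial calls) and losses; the size filters correct for
this using the **normalized size** of each copy — its length divided by
the gene's mean length among complete genomes (N50 > 3 Mb by default; for
synthetic data the generator's completeness flag can stand in, since
scaled-down chromosomes never reach real N50 values):

* a genome with **two or more copies each of normalized size > 0.75**
  marks the gene a *true duplicate*; the gene leaves the panel entirely;
* copies of normalized size **< 0.7** are discarded as fragments;
* a surviving single copy of normalized size **> 1.3** is implausibly
  long and is scored *missing*;
* a genome with exactly one surviving copy in [0.7, 1.3] is *present*;
* two surviving copies that both fall in the ambiguous band (0.7, 0.75]
  cannot be told apart (tandem short duplicates vs. a fragment pair) and
  are scored *missing* — the conservative reading, logged in the panel
  provenance;
* genes missing in **4 or more** genomes are removed.

The duplicate rule is applied per copy, not to the per-genome mean of
copy sizes: one full-length copy plus sub-0.7 fragments is a fragmented
single-copy gene, not a duplication. All decisions are recorded per gene
in the panel's provenance table and are invariant to genome input order.

### Alignment and the supermatrix

Each panel gene is aligned by translate–align–back-translate: terminal
stop codons are removed, amino acids aligned, and the alignment threaded
back onto codons so gaps come in triplets. Sequences with internal stop
codons or frame-breaking lengths are flagged and scored missing for that
gene. The aligner is a plug-in contract (named residue vector in,
equal-length aligned vector out); the bundled `toyAligner` is a
deterministic star alignment (Needleman–Wunsch against the longest
sequence, insertion columns merged) sufficient for the near-identical
sequences of a core panel, and any external protein MSA tool can be
substituted. When all sequences of a gene have equal length and no stops
the codon alignment is the identity and the translation round trip is
skipped.

Terminal codon columns are trimmed while **more than 90%** of rows are
missing there (a row's codon is missing when it contains a gap or an N;
gaps and Ns are counted jointly). Exactly-90% columns are kept; interior
columns are never removed; trimming is idempotent. The per-gene
alignments are concatenated in panel order into a supermatrix, with
genomes missing a gene N-filled across exactly that gene's partition;
partition bookkeeping is emitted in the RAxML `DNA, gene = start-end`
syntax for external partitioned inference.

### Species delimitation by PNS

The percentage nucleotide similarity between two supermatrix rows is

$$\mathrm{PNS} = 100 \cdot \frac{\#\{i : a_i = b_i\}}
{\#\{i : a_i, b_i \in \{A,C,G,T\}\}},$$

i.e. computed over the positions where both rows carry an unambiguous
base — gaps, Ns, and all other ambiguity codes are excluded from the
denominator. Two genomes are conspecific when PNS ≥ 97. Because the
pairwise criterion alone does not define a partition, species are the
connected components of the ≥97% graph (single linkage): it is the only
rule under which the pairwise criterion is both necessary and sufficient
for a merge, and it reproduces the documented behavior of near-threshold
type-strain trios. Clusters containing a type strain inherit the
alphabetically first published name (merged names are recorded and
warned about); the rest become zero-padded numbered candidates, blocked
by group in tree order.

### Gene content

Species-level occurrence is the mean copy count over member genomes,
rounded to 0 (n < 0.5), 1 (0.5 ≤ n < 1.5) or 2 (n ≥ 1.5). The stated
breaks leave [1.5, 2) formally unassigned; rounding it up to 2 is the
choice here, since a mean of 1.6 copies is better evidence for 2 than
for 1. Pairwise dissimilarity is Bray–Curtis on Hellinger-transformed
profiles (square root of row-relative abundances, `vegan::decostand` /
`vegdist`); the Hellinger step damps copy-number inflation from
fragmented assemblies. Pan/core rarefaction resamples, per replicate, a
random species order with one random genome per species — so
over-sequenced species cannot dominate — and accumulates nested subsets,
making each replicate's pan curve non-decreasing and core curve
non-increasing by construction. Venn overlaps among groups are computed
at a fixed depth of 15 sampled species per group (groups with fewer
species contribute all of them, with a warning) on the rounded species
profiles.

### Synteny

Core genes adjacent on a scaffold form a **link** (an unordered gene
pair); on a complete circular chromosome with g single-copy core genes
there are exactly g links. The synteny index between genomes is

$$SI = \frac{|L_A \cap L_B|}{\max(|L_A|, |L_B|)} \in [0, 1].$$

The denominator is not stated by the usual formulations when the two
link sets differ in size (drafts with missing genes); the maximum is
used so that SI(x, x) = 1 and missing data can only lower, never
inflate, similarity.

Draft scaffolds are ordered and oriented against reference genomes:

1. each scaffold scores the mean rank of its core genes in the
   reference order, taken **on the circle** (circular mean of ranks).
   The plain linear mean mis-places any scaffold spanning the arbitrary
   linearization origin of a circular reference (ranks {38, 39, 40, 1,
   …, 7} average to ~14 instead of ~2.5); the circular mean equals the
   linear mean for all other scaffolds and sorting circular midpoints
   preserves cyclic order, which is what circular link sets depend on.
   Ties break by scaffold id;
2. orientations are chosen by a greedy left-to-right sweep plus one
   refinement pass, maximizing the number of scaffold-junction
   adjacencies (including the circular closure) present in the
   reference; exhaustive search over the 2^k orientation assignments is
   intractable for fragmented drafts, and the sweep provably recovers
   unrearranged fragmentations. Orientation ties keep forward;
3. one candidate configuration is built per reference; the one with the
   highest SI against its reference is kept (ties by reference id) and
   its inferred circular order **joins the reference pool**. Drafts are
   processed in decreasing completeness — descending N50, ties by fewer
   scaffolds, then id — so highly fragmented genomes see the most
   references. Junction links and the circular closure of the inferred
   configuration count toward the draft's link set, keeping the
   one-link-per-gene accounting intact.

A link is *present in a species* when at least one member genome carries
it (most species hold one or two genomes; requiring a within-species
majority would make singleton absence calls erratic under assembly
noise). The consensus architecture network keeps links whose species
frequency **strictly exceeds 50%** in at least one group; the
conserved-link profile lists the links of the reference genome (highest
mean SI to all others; ties lexicographic) in chromosomal order with
per-group frequencies.

### Tree concordance

Trees built from the three data layers (supermatrix distances,
gene-content dissimilarity, synteny dissimilarity) are compared by
normalized RF distance: the number of nontrivial bipartitions unique to
either tree divided by the total number of nontrivial bipartitions in
both. This denominator degrades gracefully for polytomous (collapsed)
trees and reads as the proportion of unique nodes. Gene-tree supports in
the bracketed `():L[N]` dialect are relocated to node labels before
parsing; internal nodes with support strictly below 10% are contracted
into polytomies (nodes without numeric support are never collapsed;
supports ≤ 1 are auto-read as proportions). The concordance test
compares each observed inter-method distance to the null distribution of
RF distances between the best tree and its bootstrap replicate trees; an
observed distance above the null maximum indicates disagreement beyond
topological uncertainty. The bundled fallback inference is neighbor
joining on 100 − PNS (self-contained and deterministic); any external
ML/coalescent engine can be used through the written artifacts
(per-gene alignments, partition file, multi-tree newick, NEXUS with
taxon partition).

## The synthetic clade generator

`simulateDataset()` emulates the inputs of a real survey with known
ground truth: a fixed asymmetric species tree (ladders within and among
groups — a stable fixture rather than a birth–death draw), layered
independent-site substitutions, Poisson gene gain/loss on an accessory
pool, Poisson inversions/translocations on the circular gene order,
draft-assembly fragmentation with optional gene splitting, and noise
annotation rows. Key semantics:

* **Divergences are per-layer pairwise expectations.** The per-lineage
  substitution probability p is solved from the target pairwise
  divergence d via $(1-p)^2 + p^2/3 = 1 - d$ (uniform replacement among
  the three alternative bases), so two lineages separated at one layer
  realize divergence d in expectation, double hits included. Layers
  compound: genomes of different groups differ by roughly the sum of the
  group, species and genome layers.
* Substitutions avoid creating stop codons, keeping every gene
  translatable; gene lengths are drawn around
  `mean_gene_length_codons` (default 300 codons ≈ 900 bp, a typical
  bacterial gene).
* Accessory sequences evolve to the species level only (genomes of one
  species share them) — a cost-saving simplification that leaves
  gene-content and synteny semantics untouched.
* Rearrangements are inversions and block translocations of the full
  gene order; the genome-level rate is one fifth of the branch rate so
  that within-species architecture stays mostly intact. With the
  default `rearrangement_rate = 15` the realized SI contrast is roughly
  0.95 within species, 0.75 among species within groups and 0.6 among
  groups — the qualitative pattern of a real multi-group clade at this
  reduced genome size.
* Defaults (4 groups × 5 species × 2 genomes, 300 core genes, 400
  accessory genes, 80% drafts with 4–20 scaffolds, within/between
  species divergence 1%/5%) are a deliberately scaled-down clade: small
  enough for a complete analysis in about a minute, large enough that
  every stage (including draft reordering against a growing pool) is
  exercised.

What the generator does **not** emulate: intergenic and regulatory
sequence, read-level sequencing error, assembly-graph artifacts,
horizontal transfer of core genes (gene content changes only through
the accessory pool), annotation-string variability beyond the three
noise classes, and plasmids. Passing the recovery suites therefore
shows the pipeline's rules are implemented correctly and are mutually
consistent — not that they are robust to every pathology of real draft
assemblies.

## Numerical choices and degenerate inputs

* All unordered ties (scaffold scores, best-reference SI, reference
  choice, candidate numbering) break lexicographically — determinism
  over unspecified behavior.
* A single master seed fans out to per-stage seeds by stable string
  hashing (`stageSeed`), so toggling one stage does not change
  another's randomness; rerunning a pipeline with the same seed
  reproduces identical artifact checksums.
* The RF bootstrap null resamples supermatrix columns (up to 30,000 per
  replicate, a subsample for large matrices) and rebuilds the tree per
  replicate; 20 replicates by default.
* Zero comparable positions in a PNS pair, empty link sets, all-zero
  abundance profiles, over-trimmed alignments and threshold
  misorderings raise immediate errors rather than propagating NaNs.
* Candidate genes never seen in single copy in a complete genome cannot
  be size-normalized and are dropped with a warning.

## Problem sizes used by the test suite

The suite exercises hand-checkable fixtures (5-gene circles, 5-leaf
trees, 3-species rarefaction groups with exhaustive enumeration
oracles), threshold-flip sweeps around every rule boundary, recovery
suites (species delimitation with divergences straddling the threshold;
49 fragmented copies of a 300-gene genome reordered to full synteny
recovery), and one full default-scale end-to-end run. These sizes were
chosen so the complete suite runs in a few minutes while every stage is
tested at a scale where its combinatorics are non-trivial.

## Known limitations

* Function-string orthology inherits any annotation inconsistency
  between genomes; a gene renamed between runs of the annotation
  service is two genes here.
* Single-linkage species can chain through intermediate genomes; the
  package reports the components it found, not a proof of
  non-transitivity-free clustering.
* The greedy orientation sweep is not globally optimal for heavily
  rearranged drafts; it is exact for unrearranged fragmentations and
  close in practice otherwise.
* NJ trees are a plumbing fallback for self-contained runs, not a
  substitute for ML or coalescent inference on real data.
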