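---
title: "Calling structural variants from long reads: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling structural variants from long reads: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lrsv` detects deletions (DEL), insertions (INS), duplications (DUP),
inversions (INV) and translocations (TRA) of at least 50 bp from
coordinate-sorted long-read alignments. This vignette explains the
statistical machinery, the parameters that matter, what the bundled
simulator does and does not emulate, and the design decisions that were
genuinely open.

## Signature collection

A *signature* is a single read's worth of SV evidence, the quadruple
(type, contig, start, end) plus provenance. Two sources are scanned:

* **Intra-alignment** signatures come from I/D operations inside one
  CIGAR. Every deletion gap of at least `min_signature_size` (default
  30 bp) yields a DEL signature on its reference interval; every
  insertion gap an INS signature anchored at its position with
  `end = start + length`, so an insertion's span encodes its length.
  Same-type gaps separated by fewer than 150 bp of matched sequence are
  merged first: noisy long reads fragment one biological gap into
  several CIGAR operations, and merging them recovers the event's full
  length. The 30 bp floor deliberately sits below the 50 bp reporting
  threshold so that fragmented evidence for borderline events survives
  clustering; final calls are length-filtered at 50 bp.

* **Inter-alignment** signatures come from the geometry of a read's
  split (primary + supplementary) alignments, ordered by query offset
  (hard clips converted to read coordinates, ties broken by reference
  position). For each adjacent pair of segments, one deliberately
  lenient rule fires: different contigs give a TRA; opposite strands an
  INV; a reference backtrack of at least `min_signature_size` on the
  same strand a DUP; otherwise the difference between the
  reference-space and read-space gaps gives a DEL (reference gap
  longer) or an INS (read gap longer). No further heuristics are
  applied at this stage — separating real split-read evidence from
  alignment noise is the job of the learned filter, not of hand-tuned
  thresholds.

For inversions the pair brackets the event exactly: a
forward-to-reverse transition joins the two segment *ends*, a
reverse-to-forward transition the two segment *starts*. This recovers
both true breakpoints for reads entering the inversion from either
side as well as for fully spanning reads; the naive alternative
(reporting the inverted segment's own interval) mislocates one
breakpoint for partially crossing reads. Translocation signatures are
canonicalized so that the lower-named contig carries the `start`
coordinate; both derivative-chromosome views of one junction then fall
into the same cluster.

Every intra signature carries a 25-entry feature vector (global
alignment: MAPQ, clip lengths, indel-operation counts, edit distance,
read length, aligned fraction, supplementary count; CIGAR-local: gap
offsets, length, type code, distance to and count of other large gaps;
base distribution: A/C/G/T frequencies of the read and of a ±100 bp
window around the gap, plus the fraction of positions inside
homopolymer runs of length ≥ 5). Inter signatures carry a 22-entry
vector (primary/supplementary MAPQ, aligned lengths, clips and edit
distances; pair geometry: contig and strand consistency, read- and
reference-space gaps and overlaps, segment count, rule-inferred type
code; base distribution of the primary sequence). The feature names are
part of the public schema: a filter bundle records them and refuses to
score signatures extracted under a different schema.

## Two-step adaptive clustering

Signatures of one type are sorted by (contig, start) and swept into
coarse partitions: a new partition opens when the spatial distance to
the previous signature exceeds `partition_gap` (default 1000 bp). For
the span types (DEL/DUP/INV) the spatial distance between an earlier
signature *i* and a later signature *j* is `s_j − e_i` floored at zero —
overlapping intervals are at distance zero. The floor matters: with an
absolute value instead, two identical observations of an event longer
than the partition gap would sit at a "distance" equal to their span
and could never share a partition, making every SV above 1 kb
uncallable. For the point-like types (INS, TRA) the distance is
`|s_j − s_i|`; translocations partition on the ordered contig pair.

Each partition of local depth LD (its member count) is then refined by
average-linkage hierarchical clustering under the similarity score

```
pos_dis(i, j)  = |mid_i − mid_j|            (interval midpoints)
span_dis(i, j) = |span_i − span_j|
S(i, j)        = (pos_dis/λ + span_dis) / max(span_i, span_j)
λ              = max(1, |GD − LD| / max(GD, LD) + GD)
```

where GD, the global depth of the type, is the mean LD over that type's
partitions. Pairs merge while the linkage distance is strictly below
`cluster_threshold` (default 0.3). λ is the adaptive part: deep data
(large GD) shrinks the locus-distance term so scattered observations of
one event still merge, while partitions whose local depth deviates from
the sample norm get a slightly larger λ, loosening or tightening the
locus criterion with context. λ is clamped at 1 from below because the
raw expression can fall under 1 for GD < 1, where it would *amplify*
locus distances.

Numerical conventions, chosen for determinism where the procedure was
open: average linkage (single linkage chains, complete linkage
over-splits shallow partitions); ties at exactly the threshold do not
merge; consensus breakpoints are lower medians of member coordinates
(even-sized clusters take the smaller central value); cluster support
is the number of distinct read names, not signatures. When both spans
are zero (TRA breakends), `S = pos_dis/λ` with the denominator replaced
by 1; the threshold then acts in units of λ·0.3 bp, and the mate
coordinate's consensus is the member median. A brute-force
agglomerative oracle (exhaustive nearest-pair merging) is kept in the
test suite and must agree with the `hclust`-based implementation as a
set partition on hundreds of random inputs.

## Learned false-positive filters

Noise enters the two evidence streams differently, and the two filters
reflect that.

**Split-read filter (random forest, before clustering).** Because the
inter rules are lenient, spurious supplementary alignments produce
signatures with essentially random geometry. A random forest over the
22 normalized features classifies each inter signature into
DEL/INS/DUP/INV/TRA/false: `false` predictions are removed, and
predictions relabel a signature only across the INS/DUP boundary — the
one genuinely fuzzy pair, since a tandem duplication is an insertion
of its own copy. The other rule types are deterministic consequences
of alignment geometry (gap sign, strand, contig pair), and letting an
imperfect classifier overturn them converts every residual model error
into a guaranteed false call at a true locus; restricting the relabel
scope is what keeps general-mode precision at or above sensitive-mode
precision, the trade-off the two modes exist to provide. Hyperparameters
are grid-searched over tree depth {2,4,6,8,10}, forest size
{10,25,50,75,100} and minimum node size {10,25,50,75,100}, keeping the
model with the best held-out macro-F1. The forest backend is `ranger`
with one thread and a fixed seed, so training is reproducible;
`min.node.size` is the closest available analogue of a minimum-samples-
to-split control.

**Cluster filter (CNN, after clustering).** CIGAR gaps are individually
reliable, but clustering them produces fuzzy candidate regions (allelic
mixtures, fragmented repeats), so filtering happens at the cluster
level. Each DEL/INS cluster containing intra members is encoded as a
fixed 100 × 25 matrix: one row per member signature ordered by start
(clusters above 100 keep the 100 members nearest the consensus
breakpoint; smaller clusters are zero-filled), one column per intra
feature, min-max normalized with bounds frozen at training time
(inference clips out-of-range values — per-matrix scaling would destroy
cross-sample comparability). The network has three convolutions with
kernel sizes 3 × 25, 3 × 8 and 3 × 1, each followed by a 2-row max
pool, then three fully connected layers (320 → 256 → 64 → 3) with batch
standardization and dropout 0.5, and a softmax over {DEL, INS, false}.
The first two kernels span the full current width, so the width
collapses 25 → 8 → 16 maps; the third (3 × 1) slides down each of the
16 columns with 2 filters. An earlier literal reading in which the
third layer also collapses the width (8 → 1 map) leaves a one-channel
bottleneck whose ReLU dies under typical initializations and trains to
chance; the per-column reading uses the same stated kernel sizes and
trains reliably. The network is implemented directly in R with im2col
convolutions and hand-derived backpropagation (verified against
numerical gradients in the test suite), Adam on
cross-entropy, batch size 256, 15 epochs, learning rate 1e-3 decayed
×0.1 at each third of training (i.e. every 5 epochs under the default
15). Two training-corpus accommodations: classes are inverse-frequency
weighted in the loss, because cluster corpora are dominated by
low-depth false clusters; and small corpora get proportionally more
epochs so the total number of optimizer steps matches a 5000-example
run. Clusters of depth 1–20 are augmented by treating each member as a
starting row and drawing a wrap-around window smaller than the cluster
depth, which multiplies scarce true-cluster examples and teaches the
network depth-invariance. At inference the network's vote decides only
whether a cluster is kept or dropped: a `false` prediction removes it,
while a conflicting DEL/INS prediction does not relabel, because an
intra cluster's nominal type is fixed by its CIGAR operations — a
deletion gap cannot be an insertion, so a contrary model vote can only
be a model error.

**Filter bundles.** A bundle holds both models, their feature schemas
and their normalization bounds. Bundles are trained on demand from the
simulator (`train_filter_bundle()`, about two minutes at the default
scale) rather than shipped as opaque pretrained blobs: training is
deterministic under a seed, so a bundle is reproducible from source,
and retraining against real labeled data is the same one call. Training
labels come from `generate_labels()`: an item matches a truth event
when its breakpoints agree within 500 bp and its length within a
0.7–1.43 ratio; the label is the *truth* type, so systematically
misclassified rule output (e.g. duplications collected as insertions)
trains the filter to correct it.

In *sensitive* mode both filters are bypassed entirely and calling
relies on the lenient rules plus adaptive clustering alone — the
configuration for complex genomes (cancer) where recall is paramount
and downstream evidence review is expected.

## Support, length and genotyping

Reported calls need `min_support` distinct reads (default `"auto"`:
`clamp(round(depth/10) + 2, 2, 10)`, which gives 5 at ~30× — the value
at which callers of this family balance precision and recall at that
depth) and 50 bp of length (translocations excepted). Genotypes come
from a three-hypothesis binomial likelihood on allele counts: with
`n = ref + alt` reads and `k = alt`, the likelihoods of 0/0, 0/1 and
1/1 are `Binom(k; n, e)`, `Binom(k; n, 1/2)` and `Binom(k; n, 1 − e)`;
the genotype is the argmax and its quality the Phred-scaled ratio of
the two best hypotheses. The error index `e` is platform- and
event-specific: 0.2 (insertion-like: INS, DUP) and 0.1 (other) for CLR
and ONT; 0.1 and 0.05 for CCS. The reference count is the mean
non-alt-read depth over 500 bp flanking windows each side of the
breakpoints, clipped at contig boundaries; alt reads are excluded from
it to avoid double counting. Translocations are genotyped with the
"other" index but should be treated as low-confidence — flank coverage
is a weak reference proxy at an inter-chromosomal junction, and the
same caveat applies to duplications, whose flanks are not depleted by
the event.

## The simulator: what it emulates, what it does not

`simulate_sample()` builds a two-contig reference with planted
homopolymer runs (so repeat-content features vary), implants
non-overlapping SVs of all five types as a diploid donor, and
synthesizes alignment records directly from the donor-to-reference
block map: reads crossing a deletion carry a D operation (a split pair
above 1 kb), insertions an I operation or an unaligned-insert split,
duplications a reference-backtracking split, inversions strand-flipped
splits, and translocations cross-contig splits derived from two
consistent derivative chromosomes. Platform noise injects small
(1–8 bp) indels into CIGARs at per-base rates of 2e-3 (CLR/ONT) or
2e-4 (CCS); at `noise_rate` (default 0.1) a read receives a spurious
30–80 bp gap — sized just above the signature floor, the regime the
CNN must reject — and at half that rate a spurious low-MAPQ (20–40)
split fragment remapped to a random locus, the regime the random
forest must reject. Every read's ground truth is recorded in a
manifest.

Fixed conventions: events keep at least two read lengths of spacing
(translocation mate breakpoints are placed in the same
spacing-respecting sweep as the other events on their contig);
aligned segments shorter than 100 bp are dropped, as real aligners
rarely emit shorter supplementary alignments; heterozygous events are
assigned to a random haplotype; coverage is split evenly between
haplotypes. The default mean read length is 3500 bp — real long reads
are 10–20 kb, but 3500 is near the longest mean for which 120 spaced
slots (100 events plus 20 translocation mates) fit in the 1 Mb
default reference under the spacing rule, so it is the compromise the
desk-scale study design forces.

What the simulator does **not** emulate — and hence what passing tests
do not establish about real data: base-level error profiles and
quality scores (mismatches only adjust the NM tag), mapping ambiguity
in repetitive or low-complexity regions, nested or overlapping events,
chimeric reads, reference gaps, and aligner-specific split heuristics.
The learned filters trained on this generator transfer to its test
samples, not automatically to real platforms; retraining on real
labeled data is the supported route (`lrsv.R train`).

Two limitations follow directly from the geometry and are visible in
every full-scale run: heterozygous insertions whose length approaches
the read length leave too few spanning reads to reach `min_support`
(large dispersed insertions are a recognized weakness of
alignment-based calling generally), and inversions shorter than the
100 bp minimum segment length produce no split evidence at all.

## Problem sizes and run times

The bundled experiments use a 1 Mb reference, 100 implanted events
(50–5000 bp), 30× coverage and noise rate 0.1, with filter bundles
trained on an independent 1 Mb simulation at noise rate 0.15; filter
benchmarks use 10 000 split-read vectors and 5000 cluster matrices of
separable synthetic classes. The full acceptance script runs in about
ten minutes and the test suite in about twenty. These sizes were
chosen so a complete reproduction is an interactive-scale exercise;
nothing in the method depends on them.
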