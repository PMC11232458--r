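# lrsv — structural variant calling from long-read alignments

`lrsv` detects and genotypes the five major classes of structural
variation — deletions (DEL), insertions (INS), duplications (DUP),
inversions (INV) and translocations (TRA), all ≥ 50 bp — from a
coordinate-sorted, indexed BAM of long reads (PacBio CLR/CCS, Oxford
Nanopore) aligned to a reference. It is written for people who want an
SV caller whose every stage is inspectable and retrainable from R:
method developers, benchmark builders, and analysts working on
organisms where shipped pretrained models do not apply.

## The method in brief

1. **Signature collection.** Each read contributes signatures
   (t, c, s, e) — type, contig, start, end — from two sources: I/D gaps
   inside one CIGAR (intra-alignment) and the geometry of its split
   alignments (inter-alignment), the latter under deliberately lenient
   rules: different contigs → TRA, opposite strands → INV, reference
   backtrack → DUP, otherwise the sign of (reference gap − read gap)
   decides DEL vs INS. Each signature carries a feature vector
   (25 intra / 22 inter features).
2. **Adaptive clustering.** Signatures of one type are swept into
   partitions (spatial distance > 1000 bp opens a new one; local depth
   LD = partition size, global depth GD = mean LD). Within a partition,
   average-linkage clustering merges pairs while

   `S(i,j) = (pos_dis/λ + span_dis) / max(span_i, span_j) < 0.3`,
   `λ = max(1, |GD − LD| / max(GD, LD) + GD)`,

   so locus distance is discounted in deep data and clustering
   tightness adapts to local context. Consensus breakpoints are member
   medians; support is the count of distinct reads.
3. **Learned filtering (general mode).** A random forest classifies
   split-read signatures (6 classes incl. `false`) before clustering; a
   small CNN (kernels 3×25 / 3×8 / 3×1 over a 100×25 per-cluster
   feature matrix) classifies clustered CIGAR evidence (DEL/INS/false)
   after. `--mode sensitive` bypasses both for maximal recall.
4. **Genotyping & VCF.** A three-hypothesis binomial likelihood on
   allele support (alt fraction e, 1/2, 1−e; e platform-specific: 0.2/0.1
   CLR·ONT, 0.1/0.05 CCS for insertion-like/other events) assigns
   0/0, 0/1, 1/1; calls are written as VCF 4.2 (symbolic ALTs, BND
   pairs for TRA).

A deterministic simulator (`simulate_sample()`) builds references,
implants SVs and synthesizes noisy alignments with exact ground truth,
so the whole pipeline — including filter training — runs with no
external data.

## Worked example

```r
library(lrsv)

spec  <- simulation_spec(ref_length = 2e5,
                         n_sv = c(DEL = 4, INS = 4, DUP = 3, INV = 3, TRA = 2),
                         sv_size_range = c(100, 2000),
                         depth = 20, noise_rate = 0.1, seed = 7)
sim   <- simulate_sample(spec, "demo")
calls <- run_call(sim$bam_path, sim$ref_path, "demo/calls.vcf",
                  mode = "sensitive", min_support = "auto")
ev    <- evaluate_calls(calls, sim$svs)
cat(sprintf("precision %.2f recall %.2f\n", ev$precision, ev$recall))
for (cl in calls[1:3])
  cat(cl$type, cl$contig, cl$start, cl$end, "support", cl$support,
      cl$genotype, "\n")
```

prints (seed 7; your machine will reproduce it exactly):

```
precision 1.00 recall 0.94
INS chr1 14600 15739 support 15 0/1
INS chr1 25257 25402 support 16 1/1
DUP chr1 33697 33842 support 12 0/1
```

i.e. on this 200 kb sample with 16 implanted events every call matches
the truth set and 15 of the 16 implants are recovered (the one miss is
a 1.9 kb homozygous insertion with only three spanning reads — see the
vignette on insertion length vs read length): a heterozygous 1139 bp
insertion supported by 15 reads, a homozygous 145 bp insertion by 16,
and so on. (Coordinates are the internal 0-based convention of the R
objects; the VCF on disk is 1-based.) For general mode, first train a filter bundle:

```r
tr     <- simulate_sample(simulation_spec(seed = 101, noise_rate = 0.15), "train")
bundle <- train_filter_bundle(tr$bam_path, tr$svs, seed = 101)
run_call(sim$bam_path, sim$ref_path, "demo/general.vcf",
         mode = "general", bundle = bundle)
```

A thin command-line wrapper with `call`, `simulate` and `train`
subcommands is installed at `inst/cli/lrsv.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/lrsv.R", package="lrsv"))') \
    call --bam reads.bam --ref ref.fa --out calls.vcf --mode sensitive
```

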