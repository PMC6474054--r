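# brbtools

Post-sequencing toolkit for **early-multiplexed 3' tag bulk RNA-seq**
(BRB-seq and related barcoded oligo-dT protocols), written for
bioinformaticians who run or benchmark such libraries.

In these protocols every sample is tagged during reverse transcription with
a barcoded oligo-dT primer, so dozens of samples are pooled into a single
sequencing library. Read 1 carries the sample barcode and a unique molecular
identifier (UMI); read 2 carries the cDNA fragment. After alignment of
read 2, the pipeline's job is to (i) assign each read pair back to its
sample, (ii) count reads and deduplicated molecules per gene, and (iii)
quantify how library quality and replication affect the power to detect
differential expression. `brbtools` implements all of that, plus a
synthetic-library generator with exact ground truth so the whole pipeline is
testable end to end.

## What it computes

**Demultiplexing.** The read-1 layout is a compact structure string such as
`B6N10V5`: a 6 nt barcode, then a 15 nt UMI made of 10 fully random bases
(N) and 5 random non-T bases (V, preceding the oligo-dT). A read is assigned
to the sample whose barcode has minimal Hamming distance d ≤ `max_mismatch`,
strictly smaller than the runner-up; ties are `ambiguous`, never guessed.

**Counting.** Aligned reads are assigned to genes in union mode (as in
htseq-count): the read's CIGAR blocks are intersected with merged exons;
one overlapped gene → `feature`, several → `ambiguous`, none →
`no_feature`; NH > 1 or secondary/supplementary records → `multimapped`.
Two matrices come out: `reads[g, s]` (all feature-assigned records) and
`umis[g, s]` (distinct UMI strings per gene and sample), with
`umis ≤ reads` cell-wise guaranteed.

**QC.** Alignment-category fractions, mitochondrial rRNA contamination
(MT-RNR1 + MT-RNR2 counts over total), detected genes at count thresholds,
UMI-based duplication `1 − Σumis/Σreads`, 5'→3' gene-body coverage in
merged-exon coordinates, and log2 count correlations between libraries.

**Benchmarking.** Seeded uniform downsampling of alignment files to a fixed
read count (sampling distinct query names, keeping record order); empirical
power and ROC/PR curves against a gold-standard gene set, sweeping every
cutoff of the ranked p-value list; the analytic minimal depth for detecting
a gene expressed at `cpm`,

```
D = ceil( log(1 − prob) / log(1 − cpm/1e6) )
```

(detection = at least one read, with probability ≥ `prob`); and a
negative-binomial power simulation: counts ~ NB(μ·2^(±lfc/2), φ(μ)) with
|lfc| ~ Gamma(shape 2, scale 0.5), 10% of genes differentially expressed,
tested with a built-in moment-based Wald test and summarized as mean TPR at
FDR 0.05 per replication level.

## Worked example

Simulate a 4-sample library over a toy annotation, demultiplex, count, and
check QC — entirely in-process:

```r
library(brbtools)

d   <- tempfile(); dir.create(d)
ann <- make_toy_annotation(file.path(d, "ann.gtf"), n_genes = 50,
                           include_mt = TRUE, seed = 7)
gm  <- load_gene_model(ann$gtf)
bs  <- barcode_set(paste0("S", 1:4), c("AACCGG","CCGGTT","GGTTAA","TTAACC"))
rs  <- parse_read_structure("B6N10V5")

sim <- simulate_brbseq_library(gm, bs, rs, file.path(d, "sim"),
                               mean_molecules = 40, dup_p = 0.5, seed = 11)
demultiplex(sim$r1, sim$r2, bs, rs, file.path(d, "demux"))
#> DemuxSummary: 16460 read pairs; 16460 assigned across 4 samples; 0 unassigned

res <- count_tagged_alignments(sim$sam, gm, bs, rs, r1 = sim$r1)
res$counts
#> CountMatrices: 52 genes x 4 samples; 16460 reads, 8297 UMIs
identical(res$counts$reads, sim$truth$expected_reads)
#> [1] TRUE

round(umi_duplication(res$counts), 3)
#>    S1    S2    S3    S4
#> 0.488 0.500 0.502 0.492
```

The duplication fractions sit at ~0.5 because each molecule is amplified
`1 + Geometric(p = 0.5)` times (mean 2 reads per molecule). Detection depth
and power:

```r
depth_for_detection(cpm = c(1, 10, 100), prob = 0.95)
#> [1] 2995731  299572   29956

power_curve(replicate_levels = c(5, 20), n_sims = 10, n_genes = 1000, seed = 1)
#>   n_reps mean_tpr     sd_tpr n_sims
#> 1      5    0.126 0.05189733     10
#> 2     20    0.605 0.03597839     10
```

A gene at 1 CPM needs ~3M reads to be seen 95% of the time, and moving from
5 to 20 replicates per group roughly quintuples the fraction of true DE
genes recovered at FDR 5% under the default effect-size model.

A command-line interface exposing the same stages
(`demux`, `count`, `qc`, `downsample`, `eval`, `simulate`) ships as
`inst/scripts/brbtools`; every run writes a manifest JSON with parameters,
input digests and seeds.

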