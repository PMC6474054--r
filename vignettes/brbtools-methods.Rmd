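---
title: "Models and methods behind brbtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind brbtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`brbtools` processes early-multiplexed 3' tag RNA-seq libraries — protocols
in which every sample is barcoded at reverse transcription with a barcoded
oligo-dT primer and all samples are pooled into one library — and evaluates
how such libraries perform for differential-expression (DE) analysis. This
vignette explains the models and conventions the package commits to, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## The read model

Read 1 of a pair carries the sample tag; read 2 carries cDNA. The tag
layout is described by a structure string `B<b>N<n>V<v>`:

* **B** — the sample barcode, `b` bases (at least 1);
* **N** — fully random UMI bases, any of A/C/G/T;
* **V** — random non-T UMI bases. The V segment sits immediately upstream
  of the oligo-dT stretch; excluding T prevents the UMI from bleeding into
  the dT run and makes the UMI/dT boundary unambiguous.

The package's reference layout is `B6N10V5` (6 nt barcode, 15 nt UMI), but
the structure is always an explicit input — published barcode sets imply
their lengths rather than stating them, so nothing is hardcoded.
`extract_tag()` is pure positional slicing; reads shorter than the full
structure are flagged `too_short` and counted in the demultiplexing
summary rather than guessed at.

## Demultiplexing policy

`match_barcode()` assigns an observed barcode to the sample whose barcode
has minimal Hamming distance, subject to (i) distance ≤ `max_mismatch` and
(ii) the minimum being strictly unique. Ties within tolerance return
`ambiguous`; an `N` counts as a mismatch against every base. The default
`max_mismatch = 0` is deliberately strict: common barcode sets are not
guaranteed error-correcting, so one-mismatch rescue is an explicit opt-in
(`max_mismatch = 1`) rather than a silent default.

Assigned read-2 records are written per sample with
`_<BARCODE>_<UMI>` appended to the read name. That grammar makes the
counting step self-contained: a demultiplexed FASTQ (or the BAM aligned
from it) carries everything needed, with no further access to read 1.
Counting equally accepts the pre-demultiplexing layout — read-1 FASTQ plus
aligned read-2 records joined by query name — which is the arrangement when
alignment precedes the second demultiplexing step.

Trimming (`trim_read2()`) is optional and conservative: earliest adapter
occurrence removed with everything 3' of it, then a trailing poly-A run of
at least `polya_min_run = 10`; reads shorter than `min_len = 20` after
trimming are dropped and counted. Adapters default to none.

## Gene assignment and counting

`load_gene_model()` reduces a GTF to per-gene merged exon intervals
(overlapping or adjacent exons of one gene are unioned), keeping strand and
chromosome. Internally coordinates follow the 0-based half-open convention;
GTF input is read as 1-based inclusive.

`assign_reads()` implements union-mode assignment, the default of
htseq-count: the reference ranges consumed by CIGAR `M`/`=`/`X` (and `D`)
operations form the read's blocks, `N` operations split them, and the union
of genes overlapped by any block decides the outcome — exactly one gene is
`feature`, several are `ambiguous`, none is `no_feature`. Records flagged
unmapped are `unmapped`; secondary/supplementary records or NH > 1 are
`multimapped`, with no MAPQ cutoff (mirroring the aligner's own
unique/multiple split). Intersection-style modes are out of scope.

Strandedness defaults to `forward` — in this read layout read 2 is
sequenced in the mRNA sense, so the read strand must equal the gene strand —
but remains configurable (`reverse`, `unstranded`) because the correct
setting is a property of the library chemistry, not of the counting
algorithm.

UMI collapse is exact string identity per (sample, gene): `umis[g, s]` is
the number of distinct UMI strings among feature-assigned reads. No
mismatch merging of UMIs is attempted; at 15 nt and bulk depths,
sequencing-error-induced UMI inflation is small compared to the modelling
cost of network-based collapse. UMIs containing `N` contribute to read
counts but never to UMI counts — an ambiguous base makes molecule identity
unverifiable. Genes and samples with zero counts are kept as explicit
zeros, so matrix dimensions are fixed by the annotation and sample sheet.

## QC metrics

* **Alignment breakdown** — the five category fractions per sample
  (`mapped_to_genes`, `no_feature`, `ambiguous`, `multimapped`,
  `unmapped`), summing to 1 over records.
* **Mitochondrial rRNA fraction** — counts on MT-RNR1 and MT-RNR2 over
  total. These two genes dominate mitochondrial contamination in this
  class of libraries, so the estimate deliberately uses only them; the
  gene list is a parameter.
* **Detected genes** — genes with count strictly above each threshold
  (`0, 1, 5, 10` by default); non-increasing in the threshold by
  construction.
* **UMI duplication** — `1 − Σumis/Σreads` per sample, the unbiased
  UMI-based estimator. Coordinate-based duplicate marking (as in dedicated
  tools) measures a different quantity and is out of scope.
* **Gene-body coverage** — aligned bases mapped into spliced
  (merged-exon) coordinates, oriented 5'→3' (reversed for minus-strand
  genes), scaled to the unit interval by exonic length and binned
  (100 bins). Binning in spliced rather than genomic coordinates is what
  makes the profile comparable to transcript-based coverage tools. The
  profile is reported both raw (base counts; their total equals the number
  of aligned bases used) and scaled to max = 1 so shapes are comparable
  across depths. Genes shorter than `min_gene_len = 100` are excluded as
  their bins would be undersampled.
* **Correlation** — Pearson r on `log2(count + 1)` over the gene
  intersection. The pseudocount of 1 is the conventional zero-handling
  choice; with it, doubling a library is no longer an exact affine map on
  the log scale, so replicate correlations are asymptotically rather than
  identically 1.

## Downsampling

Depth-matched comparisons require equal aligned-read counts.
`downsample_alignments()` samples at the alignment level, not FASTQ level,
so duplicate/UMI structure survives: a uniform without-replacement draw of
`target_n` distinct query names, keeping all records of a selected name and
preserving record order. The RNG is R's Mersenne-Twister with the
`"Rejection"` sampling kind, seeded from the user's integer; the manifest
records generator, seed and input digest so the claim of reproducibility is
checkable. `replicate_downsamples()` produces `k` files (default 10, the
customary number for depth-matched benchmarking), replicate `i` at seed
`base_seed + i − 1`, so a single replicate reproduces a plain call at the
base seed.

The choice to sample distinct query names (rather than records) keeps
mates and secondary alignments of one read together; the alternative would
let a read's records be split across the selection boundary.

## DE evaluation against a gold standard

Given a DE result table (`gene_id`, `log2fc`, `pvalue`, `padj` — produced
by any DE tool), `filter_de()` applies the standard |FC| ≥ 2, FDR ≤ 0.05
cutoffs; `empirical_power()` reports how many calls fall in a gold-standard
positive set and the recovered fraction (TPR). The gold standard is
self-assigned: the DE set of the deepest reference dataset is the positive
set, all other expressed genes the negatives.

`roc_pr_from_ranked()` sweeps every cutoff of the ranked p-value list; at
each unique p-value, genes at or below it are "called" and FPR, TPR and
precision are computed. Genes in the universe but missing from the table
are penalized with p = 1 rather than dropped, keeping the universe fixed
across compared methods. AUCs are trapezoidal integrals over the swept
points; the ROC curve is anchored at (0, 0) and the PR curve at recall 0
with the earliest cutoff's precision — without that anchor a perfect
ranking would integrate to less than 1 purely as a discretization
artifact. Rolling-mean formulations of the AUC agree with the trapezoid on
fine grids.

`depth_for_detection()` answers "how deep must I sequence to see a gene at
`cpm`?": each read hits the gene with probability `cpm/1e6`, detection is
at least one read, and the smallest depth with detection probability ≥
`prob` is `ceil(log(1 − prob)/log(1 − cpm/1e6))` — with `prob = 0.95`, the
conventional reliability level. The tests bracket this closed form with
Monte-Carlo binomial simulation.

## The power simulation

`estimate_nb_params()` fits the empirical model: median-of-ratios size
factors (implemented directly — six lines — and cross-checked in the test
suite against the DESeq2 reference implementation), gene-wise
method-of-moments dispersion `max((v − m)/m², 0)` with variances pooled
within groups, and a log-linear mean–dispersion trend.

`simulate_de_counts()` draws a two-group experiment: exactly
`round(frac_de × n_genes)` genes are DE (default 10%), their |log2 fold
change| from a narrow Gamma distribution with random sign, and both group
means shifted symmetrically, `μ·2^(±lfc/2)`. Counts are NB with dispersion
from the trend. Defaults where the empirical model is not supplied:
baseline means log-normal (meanlog 3, sdlog 1.5 — medians around 20
normalized counts with a realistic dynamic range), trend
`φ(μ) = 0.1 + 1/μ` (asymptotic biological CV² of 0.1 plus shot-noise-like
inflation at low counts), and Gamma(shape 2, scale 0.5) fold changes
(mean |lfc| = 1, i.e. two-fold, with few extreme effects). The gamma
parameters of the effect-size distribution are declared package defaults,
not estimates; they are configurable. Dropout modelling is omitted — this
simulator targets bulk libraries where dropout is secondary.

`nb_two_group_test()` is intentionally basic plumbing so that power curves
are self-contained: a Wald test on the difference of log normalized group
means, variance `(m + φm²)/n` per group propagated through the log with a
pseudocount of 0.5, referred to a t distribution with `n1 + n2 − 2` degrees
of freedom (the t reference, rather than the normal, is what keeps the test
calibrated at small replicate numbers), and BH adjustment. All-zero genes
get p = 1 and lfc = 0. It does not reproduce shrinkage-based DE frameworks,
and externally produced tables are first-class inputs everywhere.

`power_curve()` averages the TPR at FDR 0.05 over `n_sims` simulated
datasets per replication level. At the package defaults the expected
qualitative behaviour — a large power gain from 5 to 20 replicates per
group — is reproduced; the acceptance script reports the actual numbers at
1000 genes and 20 simulations per level, a scale chosen so the whole
analysis completes in seconds while leaving Monte-Carlo error well below
the effect being demonstrated.

## The synthetic-library generator

`make_toy_annotation()` and `simulate_brbseq_library()` generate complete
runs with exact ground truth. Per molecule: a UMI (N bases uniform on
A/C/G/T, V bases uniform on A/C/G), a fragment start drawn from an
exponential distribution of the distance to the 3' end of the merged-exon
body (`bias_decay`, default mean 200 nt — strong 3' concentration as these
protocols produce, since reads are primed from the poly-A tail), and a PCR
duplication factor `1 + Geometric(p)` (default `p = 0.5`, mean 2 reads per
molecule; geometric because amplification is multiplicative and
heavy-tailed, and a single parameter suffices). Each read gets independent
per-base substitution errors on the cDNA read at `error_rate`. Molecule
counts per (gene, sample) default to NB(mean 60, dispersion 0.3).

Aligned records carry correct chromosome, position and CIGAR (with `N`
operations across introns); configurable fractions of molecules are
emitted as unmapped, multimapped (NH = 2 with a decoy secondary record) or
intergenic instead. The special fractions apply at the molecule level — all
reads of one molecule share the category — which keeps the expected count
matrices exactly derivable from the molecule table. Transcript sequence is
synthetic random DNA: truth is positional, and no reference genome is
involved.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: base-quality structure (all qualities are
constant), indels and soft-clipping, barcode cross-talk from index
hopping, fragment-length variation, genome-wide mappability artifacts, and
the dependence of degradation on RNA quality. Tests against this generator
establish that the pipeline's bookkeeping is exact and its statistics
calibrated under the declared model, not that any particular real library
meets that model.

## Numerical and degenerate-input conventions

* Sequences are uppercased before any comparison; qualities are never
  used for matching.
* Empty inputs produce empty-but-valid outputs (zero-count summaries,
  zero matrices, header-only SAM), not errors; impossible requests
  (downsampling beyond the available reads, ROC with an empty class) are
  errors stating both numbers.
* All file writes are atomic (temp file + rename) so interrupted runs
  never leave half-written outputs.
* Every stochastic routine takes an integer seed and restores the
  caller's RNG state; identical seeds give byte-identical files.
* Fractions with zero denominators (empty samples) are reported as 0 and
  flagged by the accompanying totals rather than NaN.

## Known limitations

Demultiplexing loads the FASTQ pair into memory via Biostrings rather than
streaming, which is comfortable for benchmarking-scale and test-scale
libraries but not for full production flow cells. Quality-aware barcode
rescue, droplet-style whitelisting, transcript-level quantification,
multimapper rescue and UMI mismatch-collapse are deliberately out of
scope. The built-in DE test is a calibrated convenience, not a replacement
for purpose-built DE frameworks.
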