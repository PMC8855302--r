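# mztdecay

Analysis toolkit for **zygotic-genome-activation-dependent maternal mRNA
decay (Z-decay)** during the maternal-to-zygotic transition (MZT) in early
embryos. It is aimed at researchers profiling zygote / 2-cell / 8-cell
embryos by spike-in-calibrated RNA-seq and complementary bench assays
(RT-qPCR, immunofluorescence, 3′-ligation RACE of mRNA tails) who want the
complete downstream arithmetic — normalization, classification, fold
changes, set overlaps, tail calls — as tested, reusable functions.

## What it computes

**Spike-in normalization and copy-number dynamics.** Because total mRNA
content changes drastically across the MZT, between-sample comparison is
anchored on exogenous ERCC spike-ins. For sample *j* the scale factor is
the median-of-ratios

&nbsp;&nbsp;&nbsp;&nbsp;*s<sub>j</sub>* = median<sub>g∈spike-ins</sub> ( ref<sub>g</sub> / FPKM<sub>g,j</sub> ),&nbsp;&nbsp; ref<sub>g</sub> = geometric mean over samples of FPKM<sub>g,·</sub>

after which genes with FPKM < 1 in every sample are excluded and remaining
values < 1 floored to 1. Relative total mRNA copy number per group is the
replicate-averaged sum of normalized gene values with a chosen baseline
(e.g. WT zygote) set to 1.0. Replicate agreement is checked by Spearman
rank correlation.

**Transcript classification.** Genes are partitioned by the WT
zygote→2-cell change: ratio zygote/2-cell > 2 ⇒ *maternal decay*; ratio
2-cell/zygote > 2 ⇒ *zygotic activated*; otherwise *stable* (boundary
ratios fall to stable so the three groups always partition the universe).
Per-group median trajectories and knockdown/WT median fold changes
quantify how a knockdown blocks decay or activation; fold-threshold
up/down sets feed the overlap analyses.

**Overlap enrichment.** Intersection counts, percentages (one decimal,
half-up — the style of "3014 out of 3515 (85.7 %)"), exact three-way Venn
regions, and one-sided hypergeometric enrichment P(X ≥ k) computed in log
space so overlaps with log10 P below −1000 remain quantifiable.

**Tail analysis.** 3′-ligation RACE reads (`anchor + A^a + T^u + linker`,
U sequenced as T) are parsed into poly(A) length and terminal oligo(U)
length; uridylation frequency is summarized by poly(A)-length bin
(default: < 20 nt vs ≥ 20 nt).

**Assay quantification.** ΔΔCT qPCR fold change (ΔCT = CT(gene) −
CT(reference); fold = 2^−ΔΔCT) with replicate SEM and Welch t-test, the
immunofluorescence signal S = A<sub>d</sub>(S<sub>a</sub> −
S<sub>ba</sub>) / (A<sub>a</sub>(S<sub>d</sub> − S<sub>bd</sub>)), and
cytoplasm/nucleus signal proportions.

**Synthetic data with ground truth.** Seeded generators emit an
expression matrix (three dynamic classes, constant spike-ins, a
knockdown that stabilizes decay transcripts and suppresses activation,
log-normal noise), RACE reads with known tails, qPCR tables with a known
fold change, and IF measurements with a known signal — so every stage of
the pipeline is testable against truth.

## Worked example

```r
library(mztdecay)

sim  <- generate_mzt_experiment(simulation_params(seed = 42))
norm <- normalize_expression(sim$matrix)   # spike-in scaling + floor at 1

total_copy_change(norm, "zygote", "WT")
#>    stage condition n_replicates relative_total
#> 1 zygote        WT            2      1.0000000
#> 2  2cell        WT            2      0.5249411
#> 3 zygote        KD            2      0.9998796
#> 4  2cell        KD            2      0.6672227
```

Total mRNA halves across the WT zygote→2-cell transition (maternal decay
outweighs zygotic transcription), and the knockdown leaves the 2-cell
embryo with abnormally high mRNA content (0.67 vs 0.52) — decay is
blocked.

```r
cl <- classify_genes(norm)
table(cl$class)
#>    maternal_decay zygotic_activated            stable
#>               300                70               240

tr_wt <- median_trajectory(norm, cl, "WT")
tr_kd <- median_trajectory(norm, cl, "KD")
median_fold_change(tr_kd, tr_wt, "maternal_decay", "2cell")
#>            class stage fold_change direction reported_fold
#> 1 maternal_decay 2cell    2.304629 increased      2.304629
```

The classifier recovers the generator's 300/70/240 class design, and the
median level of maternal-decay transcripts is 2.3-fold higher in the
knockdown at the 2-cell stage — the simulated stabilization (2.32) read
back from the data.

```r
ds <- differential_sets(norm, "2cell", "KD", "WT")      # >2-fold sets
truth_up <- gene_set(sim$truth$gene_id[sim$truth$class == "maternal_decay"],
                     "decay_truth")
overlap_fraction(gene_set(ds$up, "up_in_KD"), truth_up,
                 universe_size = length(ds$universe))
#> <overlap_result> up_in_KD (n=283) vs decay_truth (n=300): 283 shared
#>   (100.0% of up_in_KD, 94.3% of decay_truth)
#>   enrichment: P = 8.14e-155 (log10 P = -154.1), universe N = 610
```

Every transcript upregulated > 2-fold in the knockdown is a true
maternal-decay transcript, and the overlap is astronomically enriched
over the 610-gene universe.

A command-line wrapper over the same functions (subcommands `normalize`,
`classify`, `overlap`, `tails`, `qpcr`) ships at
`system.file("cli/mztdecay.R", package = "mztdecay")`.

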