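---
title: "Methods and design of the mztdecay pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mztdecay pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mztdecay)
```

# The biological setting

During the maternal-to-zygotic transition (MZT), the embryo destroys the
mRNA stockpile deposited by the oocyte while switching on transcription
from its own genome (zygotic genome activation, ZGA; the major wave occurs
at the late 2-cell stage in mouse). One arm of this clearance — Z-decay —
depends on zygotic gene products: decay factors translated after
fertilization deadenylate maternal transcripts, terminal uridylyl
transferases add short oligo(U) tails to the shortened poly(A) ends, and a
3′–5′ exonuclease removes the uridylated RNAs. Blocking any step both
stabilizes maternal mRNA and impairs ZGA.

`mztdecay` implements the quantitative arithmetic of such a study
downstream of an FPKM expression matrix: spike-in normalization, transcript
dynamic classification, knockdown-effect quantification, gene-set overlap
enrichment, mRNA 3′-tail analysis, and the closed-form qPCR and
immunofluorescence quantifications. Read alignment, transcript assembly,
and FPKM estimation are upstream of this package; statistical
differential-expression testing with dispersion models is deliberately not
part of it (the analyses replicated here use pure fold thresholds).

# Spike-in normalization

Absolute mRNA content changes several-fold across the MZT, so library-size
normalization (which forces equal totals) would erase exactly the signal
of interest. Instead, samples are calibrated on exogenous ERCC spike-ins
added at fixed amounts per embryo: after scaling, a transcript's value is
proportional to its copy number per embryo.

The paper-style inputs state *that* FPKM values are ERCC-normalized but
not *how*; we chose a **median-of-ratios** estimator, the robust standard
for this problem. Each spike-in species $g$ gets a reference level
$\mathrm{ref}_g$, the geometric mean of its values across samples, and
sample $j$ receives the factor

$$ s_j = \operatorname*{median}_{g \in \text{spike-ins}}
   \frac{\mathrm{ref}_g}{v_{gj}}. $$

The median over species tolerates dropout or misbehavior of individual
spike-ins; the geometric-mean reference keeps the output on the input FPKM
scale. Numerical choices:

* zero spike-in values are treated as *missing* for the median, never as
  infinite ratios; a sample with more than half its spike-ins missing
  triggers a warning, and a sample with no usable spike-in is an error
  (normalization is then impossible);
* the fitted reference is stored in the result
  (`$spikein_reference`), and by construction the median ratio of the
  reference to every normalized sample's spike-ins is exactly 1;
* rescaling one input column by $c$ moves the geometric-mean reference by
  $c^{1/n}$, so normalized values are defined up to one global constant:
  every between-sample and between-gene ratio — and therefore every
  downstream result (totals, classifications, fold changes, sets) — is
  invariant under per-sample rescaling, while the absolute scale stays
  anchored to the observed FPKM magnitudes. A strictly invariant variant
  would need a scale-free reference and would lose the FPKM scale on
  which the floor-at-1 rule below is defined.

**Exclusion and flooring.** Genes below 1 FPKM in every sample are
removed; remaining values below 1 are set to 1. This floor guarantees
finite ratios without pseudocounts and reflects that sub-1-FPKM
differences are noise at this sequencing depth. Spike-ins are exempt from
both rules and from every downstream gene count. We apply the rules
*after* spike-in scaling — the floor is a convention on the final
normalized scale; whether the original analyses floored before or after
scaling is unstated, so this order is a documented package decision, not
an inference about the authors' intent. The operation is idempotent.

**Replicate QC** is pairwise Spearman rank correlation (average ranks for
ties) within each stage × condition group, computed over non-spike-in
genes; groups with a single replicate are skipped with a message.

# Transcript classification and knockdown quantification

Genes are classified by their WT zygote → late-2-cell change, with
replicates aggregated by arithmetic mean before ratios (the inputs are
silent on the aggregation; the mean is the least-surprising default and is
exposed through the floored values the caller supplies):

* ratio zygote/2-cell $> 2$ → **maternal decay** (group 1);
* ratio 2-cell/zygote $> 2$ → **zygotic activated** (group 2);
* otherwise → **stable** (group 3).

The published thresholds are strict inequalities on both sides, which
leaves ratios exactly equal to 2 unassigned; we place boundary ratios in
*stable* so the three groups always partition the retained universe. Two
structural properties follow and are tested: the group sizes always sum to
the universe, and swapping the two stages swaps groups 1 and 2 exactly.

Knockdown effects are summarized per group as the ratio of group medians
(knockdown/WT) of replicate-averaged values at a stage. Folds below 1 are
also reported on the conventional "decreased by $1/f$-fold" scale.
Fold-threshold differential sets (`up`: test/reference $> f$; `down`:
reference/test $> f$; strict, default $f = 2$) feed the overlap analyses.
The degraded-in-WT reference set used in overlap figures has its own
threshold ($> 3$-fold), passed explicitly rather than conflated with the
classification fold.

# Overlap enrichment

Overlap percentages are printed as $100\,k/|A|$ rounded to one decimal
with the **half-up** tie rule (matching the quoted style, e.g. 85.7 %);
base R's `round()` rounds half to even and would differ at exact ties.

Enrichment is the one-sided upper-tail hypergeometric probability
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, |A|, |B|)$, computed in log
space (`phyper(..., log.p = TRUE)`) so that overlaps whose significance is
far below the double-precision underflow limit still return a finite
`log10_p` (the natural-scale p underflows to 0 and is reported as such).
The source figures label their Venn p-values "two-tailed Student's
t-test", which cannot produce a set-overlap p-value (and the printed
magnitudes, e.g. $10^{-1753}$, exceed double range); we implement the test
a statistician would use for set overlap and document the discrepancy
rather than imitate it. The universe defaults to the retained-gene
universe of the classification and is always recorded. Three-way Venn
partitions are exact per-element tabulations; their seven regions
reconstruct all set and pairwise-intersection sizes by inclusion–exclusion,
which the tests verify against an independent element-wise oracle.

# Tail analysis

A 3′-ligation RACE read carries a gene-specific anchor, the mRNA 3′ tail,
and the ligated universal linker, in sense orientation and DNA space
(U → T through reverse transcription). The tail grammar is fixed as an
A-run followed by a terminal U-run — the architecture terminal
uridylation produces. The parser locates the **rightmost** anchor match
and the **leftmost** linker match after it, takes the substring strictly
between, and reads the maximal terminal T-run (oligo(U)) and the maximal
A-run immediately 5′ of it. Any residual tail bases mean the read violates
the grammar (interleaved or non-A/T tails) and it is flagged unparseable
rather than guessed. Matching is exact by default — appropriate for Sanger
reads of TA clones — with an optional mismatch tolerance
(`max_mismatch`, via `Biostrings::matchPattern`). Reads are assumed
sense-strand. Parsing is invariant to sequence content outside the
anchor–linker span, which the tests check by prepending and appending
arbitrary context.

Uridylation is summarized by poly(A)-length bin with the short bin
defined strictly as $< 20$ nt, the length range below which
uridylation-primed decay intermediates accumulate. "Uridylated" means a
terminal U-run of at least `min_u = 1` nt by default — no minimum is
defined in the source analyses — and the threshold is exposed.

# Assay quantification

**qPCR.** Per replicate, $\Delta C_T = C_T(\text{gene}) -
C_T(\text{reference gene})$; the contrast is $\Delta\Delta C_T =
\overline{\Delta C_T}(\text{test}) - \overline{\Delta C_T}(\text{ref})$
and the fold change $2^{-\Delta\Delta C_T}$. The published equations are
population-level; for replicate statistics we keep the per-replicate fold
distribution $2^{-(\Delta C_{T,i} - \overline{\Delta C_T}(\text{ref}))}$
and report its SEM (the $\Delta C_T$-scale SEM is also emitted, since the
scale of the published SEMs is unstated; fold-scale is the default).
Significance is a Welch (unequal-variance) two-sided t-test on replicate
$\Delta C_T$ values — the inputs say only "two-tailed unpaired Student's
t-test", and Welch is the safer reading for $n = 3$ biological
replicates. Two identities pin the arithmetic: shifting every test
$C_T(\text{gene})$ by +1 cycle halves the fold exactly, and adding any
constant to both $C_T$ values of a replicate cancels.

**Immunofluorescence.** The antibody signal is the closed form
$S = A_d (S_a - S_{ba}) / (A_a (S_d - S_{bd}))$ — background-corrected
antibody intensity, normalized by the DNA channel and the two measured
areas. $S_d > S_{bd}$ is required; $S$ is dimensionless and invariant to
joint rescaling of both channels' background-subtracted intensities.
Compartment proportions divide each compartment's quantified signal by
their sum; image segmentation itself is out of scope.

# The synthetic-data generator

The generator exists so that every pipeline stage can be tested against
known truth; its defaults are fixed study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_decay` / `n_zga` / `n_stable` | 300 / 70 / 240 | the ~6238 : 1404 : 4950 class proportions of a mouse MZT transcriptome, at a desk scale that keeps the full test suite in seconds |
| `n_replicates` | 2 | profiling was performed in duplicate per stage × condition |
| `decay_fold`, `zga_fold` | 4 | comfortably above the 2-fold classification threshold, as true decay/activation magnitudes are |
| `kd_stabilization` | 2.32 | the reported knockdown increase of group-1 medians |
| `kd_zga_suppression` | 1/4.37 | the reported knockdown decrease of group-2 medians |
| `noise_sd` | 0.1 | log-scale multiplicative noise giving replicate Spearman ≈ 0.99, matching high-quality embryo RNA-seq duplicates |
| `n_spikeins` | 20 | enough species for a stable median-of-ratios |

Noise is multiplicative log-normal on the expected abundance — the
standard choice for strictly positive FPKM-scale data, and it keeps
expected ratios interpretable. The knockdown acts only at the 2-cell
stage (zygote samples are identical in expectation across conditions),
matching an siRNA injected at the zygote stage whose effect appears
later. Per-gene baselines are log-normal (median 30 FPKM), spike-ins
log-normal (median 100 FPKM) and constant across samples before noise.
Every generator requires an explicit integer seed and restores the
caller's RNG state; identical parameters give bit-identical output.

What the generator does **not** emulate: read-level sequencing (no FASTQ,
no library-size or GC effects), transcript isoforms, per-gene variation
in effect sizes (all decay genes share one fold), correlated noise
between genes, and partial knockdown penetrance. Consequently, passing
recovery tests demonstrates that the arithmetic is correct and the
thresholds behave as specified — not that the pipeline is robust to every
artifact of real embryo RNA-seq. The RACE generator builds clean
anchor–tail–linker reads (optionally sampled from a scheme with
uridylation probability 0.8 for sub-20-nt tails and 0.1 above, the
qualitative pattern seen in decay-compromised embryos); it does not
simulate sequencing errors, which the `max_mismatch` option exists to
absorb on real reads.

# Problem sizes and tolerances

The test suite and acceptance script run the expression pipeline at 610
genes × 8 samples, RACE at 100–500 reads, qPCR at 3 genes × 3 replicates
— sizes at which every recovery target (knockdown fold within ±10 %,
classification ≥ 95 % at `noise_sd` 0.05, uridylation frequencies within
±0.05 at n = 500) has comfortable Monte-Carlo headroom under the stated
noise models, while the whole suite completes in well under a minute.
Oracle-equivalence tests (spike-in factors, Spearman, medians,
hypergeometric tail by exhaustive enumeration at universes ≤ 30, Venn
regions) use exact equality at double precision.

# Known limitations

* Normalization assumes spike-ins were added at equal amounts per sample;
  pipetting variation between samples is indistinguishable from global
  mRNA-content change.
* The three-group classification is threshold-based and inherits the
  instability of hard thresholds for genes near a 2-fold change; no
  uncertainty is attached to group membership.
* Hypergeometric enrichment treats genes as exchangeable; expression-level
  or length biases in set construction are not modeled.
* The tail parser requires the full anchor and linker to be present; it
  does not attempt alignment-based recovery of truncated reads.
* ΔΔCT assumes perfect (2-fold per cycle) amplification efficiency for
  both target and reference, as the published equations do.
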