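---
title: "Methods: scoring poly(A)-site usage beyond annotated 3' UTRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring poly(A)-site usage beyond annotated 3' UTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`pacscope` analyses 3'-end sequencing (PAC-seq) of knockdown-style
experiments to ask where transcripts end: in the annotated 3' UTR, in the
gene body, or in intergenic sequence downstream of the annotated end. The
central quantity is the per-gene, per-region **PAC-score**

$$\mathrm{PAC\text{-}score}_{g,r} \;=\; \log_2\!\mathrm{FC}\big(\text{PAC
counts in } r\big) \;-\; \log_2\!\mathrm{FC}\big(\text{PAC counts in the
annotated 3' UTR}\big),$$

for region class $r \in \{\text{intron}, \text{cds},
\text{downstream10k}\}$, both fold changes from the same treated-vs-control
contrast. Because a change in transcription or stability moves the counts
of *every* region of a gene by the same factor, that common factor cancels
in the difference: the PAC-score isolates the *redistribution* of cleavage
events between regions. A positive score means cleavage shifted toward the
region; `pac_score()` exposes a `sign` argument because the subtraction
order can be stated either way around — we fix the orientation so that
"higher score = more usage of the region's sites after treatment", which is
the interpretation the quadrant analysis relies on.

Genes quantifiable in all three metrics (region log2FC, 3' UTR log2FC,
RNA-seq log2FC) are placed into quadrants: QI (expression down, score up),
QII (both up), QIII (expression up, score down), QIV (both down), with
exact zeros or missing components left unclassified. Quadrant boundaries
sit at zero; the stricter thresholds (score $> 0.5$, expression log2FC
$< -0.25$) are used only for deriving the QI gene set, and a gene must pass
them in at least 2 contrasts (cell lines) to enter the set.

# Region construction

Four stranded region classes are built per gene from an Ensembl-dialect
GTF (protein-coding genes; transcripts tagged `retained_intron` are
dropped because their "intronic" sequence is exonic in those isoforms and
would blur the intron class):

* `utr3` — union over the gene's transcripts of annotated 3' UTRs, each
  extended 300 nt in the direction of transcription. The extension absorbs
  cleavage just beyond annotated ends, which is common because 3'-end
  annotation is imprecise.
* `cds` — union of annotated CDS features.
* `intron` — gene span minus merged CDS minus the gene's extended 3' UTR.
  By this recipe 5' UTR exonic bases remain in the class; it is "the rest
  of the gene body", and we keep the recipe rather than subtracting 5'
  UTRs because the class is defined operationally by the subtraction.
* `downstream10k` — a 10-kb window from the gene's 3' end (the strand-aware
  end of the gene span), minus **all** same-strand exons and extended 3'
  UTRs, own or neighboring; opposite-strand features are kept because a
  same-stranded 3'-end library cannot produce reads from them. The 10-kb
  width trades off capturing distal intergenic cleavage against running
  into neighboring genes.

Two points were genuinely open and are decided here, once: (i) the
*extended* 3' UTR (not the raw annotation) is what gets subtracted when
building the intron and downstream classes — this guarantees the four
classes are pairwise disjoint per gene, which the per-base oracle tests
assert; (ii) downstream windows are not truncated at neighbor gene starts —
only same-strand exons/3' UTRs are carved out, following the subtraction
rule literally. Interval algebra is delegated to GenomicRanges
(`reduce`/`setdiff`/`psetdiff`), with `merge_intervals()` /
`subtract_intervals()` exposing bedtools-subtract semantics (touching
intervals merge; subtraction of an empty set is the identity). Coordinates
are 1-based closed inside R (the GRanges convention); BED import/export
converts to 0-based half-open at the boundary.

# Read processing and counting

* **Tail detection** (`trim_polya`): the tail is the longest suffix that
  ends at the read's 3' terminus, starts at an A, and contains at most 2
  non-A bases (sequencing-error tolerance; configurable — the underlying
  protocol description states no tolerance). A read is poly(A)-derived
  when the tail holds ≥ 25 A. Reads whose tail consumes the whole read
  carry no mappable insert and are discarded.
* **Site calling**: the cleavage position is the 3'-most *aligned* base
  (alignment end on `+`, start on `-`); soft-clipped bases are ignored.
* **Internal-priming filter**: a site is an artifact when the genomic 20
  nt immediately 3' of it, read on the transcript sense strand, contain
  more than 12 A (for `-` strand sites: plus-strand T at decreasing
  coordinates). Such A-tracts can prime oligo(dT) reverse transcription
  and fake a tail. The scan counts sense-strand A only; whether both
  strands should be scanned was open, and sense-only is the
  mechanistically motivated choice.
* **Clustering** (`cluster_sites`): single-linkage with a 25-nt gap,
  matching typical cleavage heterogeneity; the representative is the
  highest-support member, ties resolved toward the 3'-most position. The
  gap is configurable since the upstream pipeline this mirrors does not
  publish its value.
* **Counting** (`count_by_feature`): strand-specific assignment of each
  cluster's position into the region classes. Within one class, a site
  overlapping intervals of more than one gene is ambiguous and discarded
  (counted, not fractionally split — fractional splitting would make
  counts non-integral and double-use reads).

# Differential testing

Counts are cpm-normalized against plain library sizes (the methods this
package mirrors state cpm, so no TMM). Units pass when the condition-mean
cpm exceeds 2 in *every* condition ("across all experimental conditions"
read as condition means, the weaker and more symmetric reading) and when
the summed count reaches 5 in at least one condition (the support rule's
scope — per sample, condition, or dataset — was unstated; per-condition
totals are the middle ground and configurable).

The differential test is a deliberately simple, self-contained stand-in
for a generalized-linear-model quasi-likelihood count test:
`log2FC = log2((mean cpm_t + 0.5) / (mean cpm_c + 0.5))` (the 0.5 prior
stabilizes low counts), and a Wald statistic on the log mean difference of
depth-scaled counts with a per-unit method-of-moments negative-binomial
dispersion floored at 0 (the Poisson limit), referred to a t distribution
with $n_1 + n_2 - 2$ degrees of freedom. The t reference (rather than
normal) compensates for estimating the dispersion from 3+3 replicates;
the package's acceptance checks assert the resulting type-I rate at
$p < 0.05$ stays within $0.05 \pm 0.02$ under the negative-binomial null
(10,000 units, mean 200, dispersion 0.1) and that power at
$|\mathrm{log2FC}| = 2$ exceeds 90% at padj < 0.1. Multiple testing uses
plain Benjamini–Hochberg: the original analysis used covariate-weighted
FDR (IHW), but the weighting covariate is unspecified, so the unweighted
step-up with identical threshold semantics (padj < 0.1) is used and
verified against a brute-force enumeration. APA events are called per gene
when ≥ 2 clusters exist and at least one is significant with a usage-
fraction change ≥ 10%; the lengthening/shortening direction is keyed to
the most distal *qualifying* cluster, a rule the upstream tool leaves
unstated (a usage-weighted mean-shift alternative would be possible; the
distal rule is simpler and matches the "most distal site gains usage =
lengthening" intuition).

# Signatures, correlations, decay

Cohort analyses standardize each gene across samples with the sample
($n-1$) SD — dropping zero-variance genes — and score a gene set per
sample as the unweighted mean Z of the set genes present (missing genes
are dropped, never imputed, and reported). Following the conventions of
the cohort analyses this mirrors, the headline correlation is Pearson's
R while p-values come from the two-sided Spearman rank test; group
comparisons use Welch's unpaired two-sided t-test (pooled variance by
flag). Whether cohort matrices are log-scale is accepted as given: Z
scores are computed on the matrix supplied.

qPCR utilities implement $2^{-\Delta\Delta C_t}$ fold changes, a
standard-curve fit ($C_t = a\,\log_{10} q + b$, slope necessarily
negative, $-3.32$ at perfect doubling), and one-phase decay
$N(t) = N_0 e^{-K (t - t_0)}$ with the plateau fixed at 0 — percent
remaining is referenced to vehicle-treated cells, so complete decay is
the natural asymptote; a free-plateau fit is available by flag. $N_0$ is
fitted rather than pinned at 100 to absorb normalization error (the
alternative was open; fitting is the conservative choice). Points before
$t_0$ (default 6 h, the first time at which decay is assumed under way)
are excluded. Fitting uses Levenberg–Marquardt (`minpack.lm`) seeded by a
log-linear regression; $K$ is constrained non-negative, fits with
$K$ below $10^{-8}$/h are flagged as "no decay" with an infinite
half-life, and $t_{1/2} = \ln 2 / K$ holds exactly for every finite fit.

# The synthetic-data generator

`sim_config()` freezes the simulated study design: 3 replicates of a
control shRNA plus 3+3 of two knockdown shRNAs per cell line, 3 cell
lines, 80 single-transcript genes on one chromosome spaced so no 10-kb
window reaches a neighbor. Each gene carries three true poly(A) sites
(3' UTR, mid-intron, 4 kb downstream of the gene end) and one recorded
internal-priming decoy 2 kb downstream. Defaults: 2,000 PAC reads per
gene per sample with NB dispersion 0.1 (RNA-seq: 500, dispersion 0.05);
25% of genes are "QI" (usage $0.70/0.15/0.15 \to 0.35/0.15/0.50$ across
utr3/intron/downstream, hence an expected downstream PAC-score of 2.74,
with expression log2FC $-1$), 10% show the reciprocal "QIII" pattern, the
rest are null with log2FC $\sim N(0, 0.15)$. Cleavage positions jitter by
a discretized normal (SD 3 nt, truncated at ±10) so each site stays one
cluster at the 25-nt gap. These effect sizes are chosen once as what a
strong regulator knockdown produces — multi-fold usage shifts and
halving of expression — and are not tuned per test.

The genome sequence is constructed so filter behavior is exact by
design: an AATAAA hexamer sits ~25 nt upstream of every true site, the
20 nt downstream of every true site contain no sense-strand A, and the
20 nt downstream of every decoy are all sense-strand A. Decoy reads are
emitted with genuine-looking poly(A) tails (≥ 25 A), so they are
removable *only* by the genomic-context filter — isolating that filter's
effect. Emitted raw reads are insert + tail with tail length
$25 + \mathrm{Pois}(10)$.

Every stochastic output derives from the master seed through labeled RNG
substreams (`annotation`, `genome`, `pac_cell_line_<k>`, ...), so
regenerating one artifact never perturbs another and all outputs are
byte-identical under a fixed seed.

What the generator does **not** emulate: sequencing errors outside the
tail, GC/fragment-length bias, multi-isoform genes, overlapping or
nested genes, microheterogeneity beyond the jitter model, and alignment
artifacts (reads are emitted pre-placed). Passing tests therefore
demonstrate correctness of the algebra, filters, statistics and
integration logic under a clean generative model — not robustness to
mapping artifacts or annotation errors in real data.

# Validation problem sizes

The test-suite and `scripts/acceptance.R` sizes are part of the package's
documented validation design: 1,000 simulated genes for the per-base
region-construction oracle; ≥ 100,000 reads for the naive-assignment
oracle; 50,000 reads/gene for the planted PAC-score recovery (analytic
value 4.0, tolerance ±0.15, and invariance to a pure expression shift);
the default 80-gene × 3-contrast study for QI gene-set recovery (≥ 95%
recovery, ≤ 1% false inclusion); 10,000 units for test calibration;
1,000 random vectors for the BH cross-check; and 100 replicate fits at 5%
multiplicative noise for decay accuracy (median half-life error < 10%).

# Known limitations

* The differential test is an approximation; on real data with complex
  mean–variance structure, an established GLM framework (edgeR, DESeq2)
  will be better calibrated. The module boundary makes swapping trivial.
* Ambiguous-site discarding slightly deflates counts in regions of
  overlapping same-strand genes.
* The intron class retains 5' UTR bases by construction (see above).
* Cohort signature scoring assumes genes are comparable after per-gene
  standardization; it does not model batch or purity covariates.
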