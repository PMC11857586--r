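---
title: "Detecting and integrating differential RNA editing from RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and integrating differential RNA editing from RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreseq)
```

# The problem

RNA editing — enzymatic alteration of transcribed nucleotides, chiefly
C-to-U (cytidine deamination) and A-to-I (adenosine deamination, read as
G by sequencers) — shows up in RNA-seq as reproducible mismatches between
reads and the encoding genome. In organisms such as the diatom
*Phaeodactylum tricornutum*, editing levels respond to chemical
elicitors, and the interesting questions are quantitative: which sites
are edited, at what frequency, does that frequency change between a
treated and a control condition, and how do editing changes relate to
expression changes of the same genes?

`dreseq` implements that analysis as a reusable pipeline over aligned
reads, a reference genome and a GFF3 annotation:

1. **calling** — per-sample pileups and editing-site detection under
   explicit filters;
2. **annotate** — genomic region, substitution class and protein-level
   consequence per site;
3. **diffstats** — one negative-binomial engine applied to site-level
   editing counts, gene-aggregated editing counts and gene expression;
4. **integrate** — Venn overlap, nine-quadrant classification, PCA of
   editing frequencies, editing/expression correlation and cohort
   reporting.

Because studies of this kind rarely deposit raw reads, the package also
ships a first-class synthetic-study generator (**synthio**) whose truth
tables make every step of the pipeline benchmarkable. All quantitative
claims below are computed by the test suite
(`tests/testthat/test-acceptance.R`) or by `scripts/acceptance.R`; the
vignette only explains them.

# Site calling

Pileups are built per sample with `Rsamtools::pileup()`, excluding
unmapped, secondary, supplementary and duplicate reads, N bases, and any
base call with Phred quality below 25 — a low-quality call never enters a
column. At each covered position the candidate alternative allele is the
most frequent non-reference base (ties broken in the fixed order
A < C < G < T). A per-sample observation is emitted iff

* depth ≥ 5, where depth = ref + alt counts *after* quality filtering,
* alternative-allele depth ≥ 3, and
* editing frequency alt/(ref+alt) within the closed band [0.10, 1.00].

A cohort site is retained iff at least 2 samples pass with frequency
≥ 0.10. For retained sites, counts are re-queried from every sample's
pileup, so a replicate with zero alternative reads still contributes its
true depth (its frequency is 0, or missing when depth is 0).

Choices worth making explicit:

* **Reference-forward reporting.** The library is treated as unstranded,
  so C-to-U editing in a minus-strand gene appears as G>A and A-to-I as
  T>C. The class mapping is C>T/G>A → C-to-U and A>G/T>C → A-to-I; the
  complement of A>G is taken as T>C, the biologically consistent pairing
  (the alternative convention pairs it with T>A, which here falls in the
  residual `other:` classes).
* **Depth definition.** Frequency uses ref+alt after quality filtering
  rather than raw coverage, so the frequency is consistent with the
  counts the filters saw.
* **Closed band.** Sites at 100% frequency are retained; fixed-looking
  sites can still be differential if absent in the other condition.
* **Multi-allelic columns.** Only the top non-reference allele is
  considered; a site whose second alternative also reaches the
  alternative-depth threshold is flagged `ambiguous` rather than split.
* **No genomic-DNA subtraction.** Every reference mismatch passing the
  filters is a candidate editing site. Without a DNA-seq control, SNPs
  and systematic mismatches are indistinguishable from editing; on real
  data the caller's output should be read as "candidate editing sites".

The caller is deterministic (independent of read order) and monotone:
raising any threshold can only shrink the retained set. On genomes under
10 kb its output is checked *exactly* against a naive recount written
directly on the SAM text.

# Annotation

Region labels follow fixed precedence: exonic > splicing > ncRNA_exonic
> ncRNA_intronic > UTR > intronic > upstream > downstream > intergenic,
with the splicing window ±2 bases inside the intron and 1 kb
upstream/downstream windows on the feature's strand (the ANNOVAR
defaults). `exonic` means inside the CDS of a coding transcript; exon
positions outside the CDS are `UTR` (kept distinct in tables, folded
into "other" in figure-style summaries). When a site is inside the CDS
of several transcripts, the longest CDS is used and the others are
recorded as secondary.

Consequences are computed on the spliced CDS in transcription order,
honouring strand and phase: the edited base is complemented for
minus-strand transcripts, the affected codon is translated with the
standard code, and the change is labelled synonymous SNV, nonsynonymous
SNV, stopgain or stoploss. The classifier is validated by exhaustive
enumeration of all 576 single-base codon substitutions against an
independent translation oracle, and by a strand-invariance property
(reverse-complementing genome, annotation and alleles preserves every
label).

# The negative-binomial engine

One engine serves three analyses. Counts are modelled as
NB(μ = s_j · q_{g,cond}, α) with log link: `s_j` are median-of-ratios
size factors (rescaled to geometric mean 1), `q` are per-condition
means, and α is the dispersion (variance = μ + αμ²).

* **Size factors** for editing analyses come from the site-level
  alt-read matrix itself, not from expression library sizes: editing
  reads are the counting unit.
* **Dispersion** is estimated per feature by method of moments on
  normalized counts pooled within conditions, then shrunk toward a
  parametric trend α(μ) = a0 + a1/μ. The trend is fitted by constrained,
  iteratively reweighted least squares on the *untruncated* moment
  estimates: truncating at zero first, or clamping a negative fitted
  intercept while keeping the slope, both bias the trend upward (the
  latter can inflate low-expression dispersions several-fold). The
  shrinkage weight defaults to prior_df/(prior_df + df) with
  prior_df = 10 — for a 3 vs 3 design (df = 4) the trend gets weight
  0.71. This is the usual empirical-Bayes moderation strength for small
  designs; with 4 residual degrees of freedom the per-feature estimate
  is noisy enough that a flat 50/50 blend leaves the Wald test slightly
  liberal under the null and visibly underpowered.
* **Testing.** Per-condition means are fitted by Newton iteration on the
  log scale with fixed α; the Wald statistic is the treated/control log
  ratio over its standard error from observed Fisher information, with a
  two-sided normal reference. All-zero features are excluded from
  testing and from the Benjamini–Hochberg correction (which counts only
  non-missing tests). A condition with zero counts everywhere gets a
  half-count continuity value, flagged `zero_group`.
* **Calls.** Differential editing (site and gene level) uses
  adjusted p < 0.05 with no fold-change gate; differential expression
  uses FDR < 0.05 and |log2FC| > 1.2. The 1.2 is on the log2 scale,
  read literally from the analysis convention this pipeline mirrors.

Equivalence with any external tool is explicitly *not* the contract —
the engine has no LFC shrinkage, no Cox–Reid adjustment and no
independent filtering. The contract is statistical behaviour, measured
by the suite on seeded simulations: null p-values uniform
(Kolmogorov–Smirnov), type-I fraction at nominal 5% within ±1.5 points,
empirical false discovery proportion ≤ 0.10 at BH 0.05 across 20 runs,
and ≥ 70% detection of planted 0.2→0.5 frequency shifts at coverage 30,
3 vs 3. On those same matrices DESeq2's defaults reach only 11–39%
detection (its minimum-dispersion floor and outlier machinery are tuned
for RNA-seq library scales, not alt-read counts), which is why the
in-repo engine is the implementation and DESeq2 only a cross-check.

Two caveats the tests make visible:

* **Scale invariance is exact only for ratios of normalized counts.**
  Multiplying one sample's column by c multiplies its size factor by c
  relative to every other sample, and normalized counts are unchanged —
  so the reported `log2FC_naive` (ratio of normalized group means, with
  a pseudocount only for zero groups) is exactly invariant. The GLM
  coefficient re-weights the deeper sample through the NB variance and
  moves slightly; this is inherent to NB GLMs with offsets.
* **Small-count discreteness.** With group means below ~15 counts, Wald
  p-values are lumpy and a KS test rejects on discreteness rather than
  miscalibration; the calibration fixture therefore uses means around
  30, matching the demo study's coverage.

TPM is computed from annotation-based gene counts and merged exonic
lengths; each sample's column sums to 10⁶ by construction.

# Integration

* **Venn overlap** is computed on host-gene identifiers — the host genes
  of significant sites vs significant editing genes vs DE genes — since
  only gene ids make the three sets comparable.
* **Nine-quadrant classification** crosses {editing up/ns/down} ×
  {expression up/ns/down}, using each axis's significance flag; genes
  missing from one table get the ns state there. Colours: both /
  editing_only / expression_only / neither.
* **PCA** of the site × sample frequency matrix imputes missing entries
  with the per-site mean (the simplest policy that keeps all samples),
  drops all-missing sites, centers sites and projects samples by SVD.
* **Correlation** pairs a target gene's per-sample mean editing
  frequency (unweighted across its sites; a depth-weighted variant is
  available) with another gene's expression, reporting Pearson R and the
  t-reference p on n−2 degrees of freedom.
* **Reporting** follows the per-sample convention: a condition's total
  editing loci is the *sum* of its replicates' locus counts, so one site
  detected in three replicates counts three times. Significant totals
  are up + down; host-gene accounting reports genes carrying upregulated
  sites, downregulated sites, and both.

# The synthetic-study generator

`sim_config()` defaults *are* the study conditions: two conditions × 3
replicates, a 0.7 Mb single-chromosome genome with 200 non-overlapping
genes (~90% coding, half with one intron, both strands, ≥2 kb intergenic
spacers so flank windows never collide), 2000 planted editing sites,
mean coverage 30×, read length 100, sequencing error rate 10⁻³.

* **Gene models** have UTRs, a CDS that starts with ATG, ends with a
  stop, has no internal stop and a length divisible by 3, and GT…AG
  intron ends. Minus-strand genes are written reverse-complemented.
* **Class mixture.** Site classes are drawn from `type_mix` first, then
  a matching reference-base position is chosen — this keeps the realized
  mixture within sampling error of the nominal one regardless of base
  composition. Defaults put 31% on C>T, 31% on A>G, 9% on each
  complementary class and 2.5% on each residual class: 80% combined
  C-to-U + A-to-I, with the C>T/A>G dominance reported for diatom
  editing surveys.
* **Frequencies.** Non-differential sites draw one Beta(2,2) frequency
  rescaled into [0.10, 1.00] (the caller's detection band; lower the
  band edge to study filter sensitivity). Differential sites get
  per-condition frequencies separated by at least `diff_margin`
  (default 0.30), balanced in direction.
* **Coverage.** Per-gene read counts are negative binomial with
  dispersion 0.01 around an abundance-weighted mean; reads start
  uniformly over the gene span ± a 300 bp read-through flank. The 0.01
  reflects near-technical replication of clonal cultures and keeps
  site-level counting noise close to the binomial sampling a 30×
  benchmark presumes; raising it toward 0.05 lowers the attainable
  power for 0.2→0.5 shifts below 60% for *any* estimator, which is
  worth knowing before designing a real study at n = 3.
* **Read-through flank.** Reads (and planted sites) extend 300 bp beyond
  annotated gene ends, emulating unannotated UTRs and transcriptional
  read-through — this is what makes upstream/downstream editing
  observable, as it is in real data. Reads are placed uniformly over the
  genomic span (pre-mRNA-like), so introns are covered too; splice
  junctions are not modelled.
* **Qualities.** Non-error bases get Q35; simulated errors get Q15, so
  the base-quality filter is exercised by construction — and, by the
  same construction, sequencing errors cannot create false positive
  calls at the default quality threshold. The caller's false-positive
  behaviour under miscalled high-quality bases is therefore *not*
  measured by these simulations.
* **Expression.** Gene abundances are lognormal (sd 0.5 on the log
  scale, E = 1); 15% of genes are differentially expressed at |log2FC|
  = 2 with random direction.

What the generator does **not** emulate: instrument error profiles,
indels, paired ends, splice-aware placement, multi-isoform genes, SNPs,
batch effects, or editing hyper-mutation clusters. Passing benchmarks on
these simulations therefore demonstrates the pipeline's internal
correctness and statistical calibration, not robustness to every
artefact of real libraries.

# Known limitations

* **Editing counts track expression.** The counting unit for
  differential editing is alternative-allele reads, which scale with
  transcript abundance; a gene whose expression doubles shows doubled
  editing reads at constant frequency. In the demo study every DE gene
  is also called at the gene editing level — visible in the Venn
  overlap. Frequency-based modelling would decouple the two layers but
  is outside this pipeline's scope, which mirrors the editing-reads
  convention.
* **No DNA control** (see above): SNPs masquerade as editing.
* **Single transcript per gene** in simulations; the annotator supports
  multiple transcripts, but isoform ambiguity ("ncRNA intronic" vs
  "splicing" style conflicts) is resolved by precedence, not modelled.
* **Benchmark sizes.** The suite runs studies of 0.22–0.7 Mb with
  800–2000 sites and the calibration fixtures use 2000-feature
  matrices; these sizes give the property checks 1–4 percentage points
  of Monte-Carlo resolution, and all thresholds quoted above are
  asserted at those sizes.

# Reproducing the analysis

```sh
Rscript analysis/01_simulate.R      # study under results/study/
Rscript analysis/02_call_sites.R    # sites.tsv + recovery scores
Rscript analysis/03_annotate_sites.R
Rscript analysis/04_differential.R  # dre_sites/dre_genes/deg/tpm
Rscript analysis/05_integrate.R     # venn/quadrants/pca/report
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
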