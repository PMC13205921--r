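---
title: "Models and design choices in heterASE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in heterASE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

heterASE analyses trio designs — an F1 hybrid grown alongside its two
inbred parents across developmental stages and planting-density
treatments — to quantify how allelic expression, expression inheritance,
deleterious-allele regulation and transcriptomic plasticity relate to
heterosis. This vignette explains each model, its assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## Parent-guided phasing

Inbred parents are (near-)fully homozygous, so a hybrid heterozygous SNP can
be phased directly: when the female parent is 0/0 and the male 1/1 the
hybrid genotype is written `0|1` (maternal haplotype carries the reference
allele), and `1|0` for the opposite configuration. `phaseTrio()` partitions
every record into exactly one label: `kept` (phased), `parent_het` (either
parent heterozygous — residual heterozygosity carries no reliable phase),
`uninformative` (parents share a homozygote), `conflict` (a parent–hybrid
combination that violates Mendelian expectation, including a hybrid
homozygous at a site where the parents are opposite homozygotes — most
plausibly a genotyping error, so it is removed rather than kept as
uninformative), and `missing`. Malformed genotype strings are rejected per
record with a count, never fatally. Multi-allelic sites and indels are
outside the model: the tables this package consumes carry biallelic SNP
genotype codes only, which avoids indel mapping bias in the allele counts.

## Population-level ASE: a Bayesian binomial mixed model

For one SNP observed across hybrids `g` and density treatments `t`, the
alternative-allele read count in a (hybrid, density) cell is modelled as

    y_gt ~ Binomial(n_gt, p_gt),   logit(p_gt) = b0 + a_g + c_t
    a_g ~ Normal(0, s_g^2),        c_t ~ Normal(0, s_t^2)

with weakly informative priors `b0 ~ Normal(0, 2.5^2)` and
`s_g, s_t ~ HalfNormal(1)`. The SNP-level ASE ratio is `plogis(b0)`.
Replicates within a cell are summed before modelling: under the model their
reads are exchangeable Bernoulli trials, and a replicate-level random effect
is deliberately out of scope.

The null hypothesis is not 0.5 but the median ASE ratio of the filtered
dataset (`computeNullRatio()`): alignment-based allele counting carries a
small global reference bias, and the dataset median absorbs it. SNPs enter
the scan when they are heterozygous in at least 10 hybrids and each retained
observation carries at least 10 reads (both bounds inclusive; the
heterozygosity count is taken before the depth filter since how many hybrids
carry a SNP is not a property of sequencing depth).

Inference is by an adaptive Metropolis-within-Gibbs sampler written in C++
(4 chains x 1000 post-warmup draws after 500 warmup iterations by default;
step sizes adapt toward a 0.44 acceptance rate during warmup only, so the
post-warmup chain is a valid fixed-kernel sampler). Two likelihood-invariant
recentering moves shift the intercept against each whole random-effect
block; without them single-site updates cross the intercept/block-mean ridge
slowly and split-Rhat degrades. Convergence is gated at split-Rhat <= 1.05
on the intercept; non-converged SNPs are excluded from the
Benjamini–Hochberg family and counted.

The reported posterior p-value is the two-sided posterior tail probability
of the ratio about the null, `2 * min(Pr(ratio < m), Pr(ratio > m))` capped
at 1 — a posterior-summary convention chosen for transparency and recorded
in the run metadata. It is conservative under the null (the posterior rarely
concentrates away from `m` by chance), which is the right behaviour for an
FDR-controlled scan: on an all-null simulation with 2000 SNPs the flagged
fraction at FDR 0.05 is essentially zero, comfortably within the 7%
calibration bound the test suite asserts.

## Per-hybrid haplotype ASE and cis/trans classification

Phased per-SNP alternative-allele counts are oriented into maternal and
paternal counts and summed over the SNPs of each gene. This per-SNP
summation assumes the input counts are free of reads double-counted across
overlapping heterozygous SNPs; the synthetic generator guarantees that, and
the assumption is stated in the run metadata. Read-level de-duplication
against BAMs is a non-goal.

Imbalance is tested with the exact two-sided binomial test against 0.5,
BH-adjusted within each hybrid x density family; genes need 20
haplotype-assigned reads by default (an artifact choice, configurable).

Regulatory patterns compare the hybrid's allelic ratio with the parental
fold change by BIC over three binomial models of the maternal read
fraction: trans-only (ratio 0), cis-only (ratio equal to the parental
log2 fold change) and cis + trans (free). A winning free model splits into
cis + trans (same direction; |ratio| below the parental fold change),
cis + trans (opposite direction; above it) and unexpected (ratio opposite
in sign to the parental DE). BIC gaps under 2 are `ambiguous` rather than
forced. The allele-specific density response tests each parental allele's
counts HPD vs LPD with a negative-binomial GLM (DESeq2 Wald test,
`fitType = "mean"`, no independent filtering — the gene set per hybrid can
be small and every tested gene should report); the response threshold is
|log2FC| > 1 at FDR < 0.01 by default, with the looser 0.05 variant
available through `responseFdr`.

## Expression inheritance

Population-level differential expression uses DESeq2 with the design
`~ stage + class + density + class:density` (class = hybrid vs inbred), DE
at FDR < 0.01 and |log2FC| > 1. Pairwise parental DE (FDR < 0.01, no fold
gate) is tiered at |log2FC| >= 1, 2, 3 (DE_2/DE_4/DE_8). SPE genes have one
parent below 0.1 FPKM and the other above 1; SPE genes with hybrid FPKM
above 1 are complementarily expressed (CE).

The D/A ratio `(F1 - mean(P1, P2)) / (max(P1, P2) - mean(P1, P2))` is
computed on replicate-mean FPKM (0 additive, ±1 dominant, beyond
overdominant); it is undefined when the parents are equal and invariant to
relabelling them. Inheritance modes are assigned per gene from replicate
counts of the trio in one condition by maximum-likelihood negative-binomial
fits of four hybrid-mean hypotheses — mid-parent (additive), either parent
(dominant) and free — compared by BIC. Numerical choices that matter:

* Dispersion is estimated gene-wise by ML with a floor of 1e-4, corrected
  for the three fitted means (factor n/(n-3)) and shrunk toward the median
  log-dispersion of the gene set (prior variance 0.1 on the log scale). At
  three replicates the raw MLE is far too unstable for calibrated
  likelihood-ratio comparisons; shrinkage toward the trend restores
  calibration, exactly as dispersion moderation does in mainstream DE
  tools.
* BIC decides additive vs non-additive first; a gap below 2 falls back to
  MP, conservatively, and is flagged. Within the non-additive family the
  free model must also beat the best dominant point hypothesis by the same
  margin, otherwise the more parsimonious dominant call stands. Without
  this second margin, chi-square noise in the dominant-vs-free comparison
  pushes roughly one dominant gene in seven into partial-dominance or
  overdominance bins.
* A winning dominant model maps directly to HP/LP; a winning free model is
  refined by D/A bands at 0.25 / 0.75 / 1.25 (configurable; the category
  scheme fixes only the ordering, not the cutoffs).

## Deleterious load

High-effect alleles are the nine SnpEff categories (frameshift, stop
gained/lost, splice acceptor/donor, gene fusion, exon loss, start lost,
transcript ablation), counted at gene level: several variants in one gene
count once. A complementary pair is a gene where exactly one parental
allele is deleterious in coding sequence. Suppression requires the
functional allele on top, |log2(functional/deleterious)| > 1, and exact
binomial FDR < 0.05, BH-adjusted per hybrid (the per-hybrid family matches
per-hybrid reporting downstream). GERP analysis is variant-level: variants
with RS > 2 carried by exactly one parent are counted per hybrid, split
into cis-regulatory (2-kb upstream) and CDS regions, and correlated with
release year, yield and heterosis.

## Transcriptomic entropy

Each sample's FPKM vector is normalised to within-sample expression
frequencies (so each sample sums to 1 — the only definition under which the
averaged frequencies form a probability vector and Shannon entropy is
proper); the per-gene frequencies are averaged over the genotype's full
stage x density sample set and `H = -sum(p log2 p)` is computed in bits.
Genes with mean FPKM below 1 across a trio's samples are removed, and the
same retained universe applies to hybrid and parents (a threshold filter
standing in for heavier clustering-based sample/gene QC). The entropy
reduction `dH = mean(H_female, H_male) - H_hybrid` is positive when the
hybrid transcriptome is more structured than its parents'; the scalar uses
the mid-parent reference, with both parental entropies also reported.
`entropyHeterosisAssociation()` correlates dH with per-hybrid heterosis.

## Phenotype statistics

Mid-parent heterosis is `F1 - (P1 + P2)/2`, percent heterosis divides by
the mid-parent value (undefined and flagged at zero). Genetic gain is an
ordinary least-squares regression of performance (or heterosis) on release
year. Two correlations are compared with the Fisher z test,
`z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3))`. For the published
comparison of ASE vs non-ASE allele-frequency correlations, the sample
sizes are read as the significant and non-significant SNP counts (2857 and
11488); that reading reproduces the printed p-value within rounding of the
printed correlations.

## The synthetic study and what it does (not) show

The generator emulates the full design: 20 hybrids with their parents by
default, stages V4/V10/VT, densities HPD/LPD, three replicates, ~500 genic
SNPs and ~1000 genes. Its defaults are the study conditions wherever those
are stated; the remaining knobs were fixed once at values a maize
transcriptomics practitioner would call realistic:

* ASE intercepts centre on ratio 0.4675 (the dataset-median reference bias
  the null is designed to absorb), SD 0.5 on the logit scale; genotype and
  treatment random-effect SDs 0.3 and 0.1; read totals
  NB(mean 100, dispersion 0.2). The NB depth model is a stand-in — the
  empirical depth distribution is not described — and is noted as such.
* Expression counts are NB with gene-wise dispersion 0.01 (biological
  coefficient of variation 0.1; each replicate pools leaves from five
  plants, which averages individual-plant variation down). Library sizes
  vary ±20% so FPKM is not a rescaled count matrix. With ~1000 genes the
  absolute FPKM scale is inflated relative to a 40k-gene transcriptome;
  silent SPE parents are therefore planted fully off, since a single stray
  read already exceeds the 0.1 FPKM silence threshold at this size.
* The inheritance mix collapses the reported category proportions to five
  planted classes (additive 0.55, dominant 0.235/0.183, overdominant
  0.015/0.017); overdominant genes are planted at |D/A| = 2 — strong
  overdominance, the regime the category is meant to capture.
* 10% of genes per hybrid form complementary deleterious pairs, half of
  them suppressed (within the reported 43.6–62.6% range) at a 4:1
  functional:deleterious allelic ratio, which feeds back into the SNP
  allele counts of those genes.
* Hybrid entropy is lowered by a per-hybrid multiplicative tilt aligned
  with log abundance (mean 0.06, SD 0.05 across hybrids). The tilt SD is
  large enough that the realised entropy reduction is essentially the
  planted quantity (correlation with the expected reduction ~0.97);
  absolute heterosis is then drawn against the expected reduction at the
  planted correlation (0.5 by default), so recovery is limited by sampling
  noise, not generator noise. GERP cis/CDS counts are planted against
  release year at correlations 0.6 and 0.0 — values chosen to be
  distinguishable at 50 hybrids, where the weak published correlations
  would be statistically indistinguishable from zero.
* All female parents share per-gene expression (and likewise males):
  parental DE structure is common across trios rather than pair-specific.
  This keeps the truth tables simple and is irrelevant to the per-trio
  statistics, but it means cross-trio heterogeneity of parental DE is not
  exercised.

Passing tests on this synthetic study demonstrate that every stage
implements its stated contract and recovers planted truth under the
design's noise model. They do not demonstrate robustness to what the
generator omits: mapping bias and double-counted reads in allele counts,
residual parental heterozygosity beyond the planted rate, batch effects,
dispersion trends varying with expression, or pair-specific parental
divergence.

## Problem sizes

The shipped tests and the acceptance script run the MCMC scan at 2000
all-null SNPs (reduced draws: 2 chains, 400 post-warmup) and 200
recovery SNPs (4 chains, 750 post-warmup), classify 1000 genes (500
planted, 500 background) for inheritance recovery, and use 50 hybrids for
planted-correlation recovery — sizes at which every calibration bound has
comfortable Monte-Carlo margin while a full run stays in the minutes range
on one CPU.

## Known limitations

Phasing requires homozygous parents; population or read-backed phasing is
out of scope. The GLMM pools replicates and models two variance components
only. Gene-level haplotype counts assume de-duplicated input. The entropy
filter is a fixed FPKM threshold, not a data-driven QC. The pipeline's
orchestration (`runPipeline()`) analyses one stage x density condition per
trio for inheritance calls; per-condition sweeps are available through the
exported per-stage functions.
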