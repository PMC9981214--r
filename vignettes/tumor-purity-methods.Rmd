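---
title: "Estimating tumor purity in PDX and syngeneic mouse models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumor purity in PDX and syngeneic mouse models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenopurity)
```

## The problem

Tumor purity — the fraction of cancer cells among all cells in a tumor — is
a basic covariate of every bulk genomic readout. In patient tumors it is hard
to measure because cancer and stromal cells share a genome. Preclinical mouse
models offer two favourable special cases:

* **PDX models.** A patient tumor fragment is engrafted in an immunodeficient
  mouse; human stroma is rapidly replaced by mouse stroma, after which the
  human-cell fraction *is* the tumor purity. Any assay that can split
  sequenced material by species measures purity directly.
* **Syngeneic models.** A mouse cancer cell line is implanted into an
  immunocompetent host of the same inbred background. All cells are mouse,
  but the cell line carries SNPs the host lacks, and the allele fractions of
  those SNPs in tumor RNA-seq encode the cancer-cell fraction.

This package implements estimators for both situations, the variant and
scoring utilities around them, and a synthetic-data module that generates
every input with known ground truth.

## Maximum-likelihood purity for syngeneic tumors

At a cell-line-specific SNP the host mouse is homozygous $HH$ while the cell
line is homozygous $TT$ or heterozygous $HT$ with allele fractions $H_1$,
$T_1$ ($H_1 + T_1 = 1$). If the tumor is a $\theta : (1-\theta)$ mixture of
cancer and host cells, a random read shows the $T$ allele with probability
$\theta$ at a homozygous site and $\theta T_1$ at a heterozygous site. With
read counts $n_H$, $n_T$, and dropping binomial coefficients that do not
depend on $\theta$:

$$\ell_{\text{HOM}}(\theta) = n_H \log(1-\theta) + n_T \log(\theta), \qquad
  \ell_{\text{HET}}(\theta) = n_H \log(1-\theta T_1) + n_T \log(\theta T_1).$$

`cohort_loglik()` sums these over the $m$ observed sites and
`estimate_purity()` maximises the sum by stepwise increment of $\theta$ over
the grid $\{0, s, 2s, \dots, 1\}$.

Numerical and design choices:

* **Grid step** `grid_step = 0.001`. The profile is smooth and (for
  homozygous-only data) unimodal, so a fixed fine grid is both simple and
  exactly reproducible; ties are broken toward the smaller $\theta$, and
  $0\log 0 \equiv 0$ so the boundary purities are evaluable.
* **Depth filter** `depth_min = 20`: sites with fewer than 20 reads are
  removed as false-positive prone.
* **Depth cap** `cap_multiplier = 5`: RNA-seq depths at different SNPs can
  differ by orders of magnitude, and a handful of very deep sites would
  otherwise dominate the sum. Sites deeper than five times the median
  retained depth are rescaled to the cap, preserving their allele fraction
  with half-up integer rounding. Rescaling (rather than discarding) was
  chosen because a deep site still carries an accurate allele-fraction
  measurement — it is the *weight*, not the value, that needs limiting;
  `cap_mode = "drop"` is available for the stricter alternative.
* **Heterozygous allele fractions.** $T_1$ defaults to 0.5 (balanced
  expression of the two alleles); an imbalance can be supplied per site, and
  `assign_genotype_class()` offers threshold-based genotype classing
  (alt fraction $\ge 0.85$ homozygous, $[0.15, 0.85)$ heterozygous) for
  callers starting from raw cell-line allele fractions.

For homozygous-only data the MLE has the closed form
$\sum n_T / \sum (n_H + n_T)$, and for balanced heterozygous-only data
$\min(1,\, 2\sum n_T / \sum n)$; the test suite holds the grid search to
those oracles within one grid step, and parameter-recovery simulations (500
sites, mean depth 50, 50% heterozygous, 200 replicates per purity level) show
bias below 0.01 and RMSE below 0.03 at $\theta \in \{0.6, 0.8, 0.95\}$.

## Deep amplicon assay for PDX purity

The assay sequences 108 short (100–300 bp) human/mouse homologous segments
with shared primer sites but divergent internal sequence, so every read is
unambiguously one species. `assay_purity()` computes each segment's human
read fraction and takes the **median** across segments (mean of the central
pair for even counts), after dropping segments below `min_depth = 100` reads
(the assay routinely sequences thousands of reads per segment, so the filter
only removes failed amplicons). The median tolerates a biased minority of
segments — amplification bias on individual amplicons is the dominant
artefact — and at 108 segments of depth 3000 the absolute error stays below
0.01 across the whole purity range in simulation.

Purity is reported as the human read *fraction*, human/(human+mouse),
assuming equal effective genome copy per cell, so that all modules share one
scale.

## Species read counting

`classify_reads()` assigns whole-library reads by comparative alignment
score: strictly better score (or mapping to only one genome) decides the
species, equal scores are ambiguous and discarded, and a configurable
`margin` (default 0) can demand a minimum score gap. The package does not
define score semantics — MAPQ, alignment score, or mismatch count all work —
because classification only uses their order. `read_fraction_purity()` then
reports the human fraction of confidently assigned reads. This estimates the
human fraction of sequenced *material*: human-exome capture in WES
over-samples human fragments and inflates the estimate, which the simulator
reproduces via a capture-bias multiplier.

## Germline versus somatic without a matched normal

PDX tumors lack matched normals, so `classify_variants()` labels a variant
germline if any independent line of evidence says it pre-dates the tumor:
population allele frequency above 0.01 in *all three* of dbSNP, gnomAD and
ExAC; presence in more than 20% of cohort models (computed cohort-wide by
`cohort_prevalence()` before per-model classification); the allele appearing
in more than one of 45 other vertebrate genomes; or a VAF below 10%. The
low-VAF rule removes subclonal and artefactual calls from the somatic set;
because its direction is unusual it can be disabled
(`apply_low_vaf_rule = FALSE`). A database with no entry is treated as
frequency zero — a rule should not fire on missing evidence — with
`missing_af = "ignore"` available to drop missing databases from the
all-of-three requirement instead. The rules combine by logical OR, so their
evaluation order is irrelevant.

`model_median_vaf()` summarises a model by the median VAF of its somatic
missense mutations when at least 30 are available; for clonal monoallelic
mutations this median is purity/2, i.e. 0.5 in a pure tumor. Real data sits
slightly lower (≈0.47) because reference-biased read mapping deflates alt
counts; the generator's `mapping_bias` multiplier (default 1, i.e. off)
reproduces that shift when wanted.

## Expression-based scoring and calibration

`ssgsea_score()` implements a rank-based single-sample enrichment statistic:
genes are ranked by expression (average ties), traversed from the top, and
the score is the sum of differences between the weighted in-set ECDF
(weights $\mathrm{rank}^{\alpha}$, $\alpha = 0.25$) and the uniform
out-of-set ECDF. It is implemented here directly — with a brute-force
running-sum oracle in the tests — and depends on expression only through
ranks, so any monotone normalisation of the input is equivalent.

`estimate_scores()` applies the stromal and immune signatures (141 genes
each; 130 stromal and 141 immune genes have mouse orthologs in the packaged
synthetic signature structure) and reports their sum as the combined score.
Three versions differ in the denominator of the purity they imply:

* *human* — human genes only: cancer-cell fraction among **human** cells;
* *mouse* — mouse orthologs only: cancer-cell fraction among **mouse**
  cells (the only applicable version for syngeneic tumors);
* *hybrid* — `hybridize_expression()` adds a human gene's expression to the
  sum of its mouse ortholog(s) (one-to-many orthologs are summed; unmapped
  genes pass through): cancer-cell fraction among **all** cells.

The hybrid version exists because stromal/immune signal in a PDX tumor is
split between residual human stroma and mouse stroma; either single-species
score sees only its share of the signal, while the hybrid sum sees all of
it. On synthetic cohorts where the split varies by sample, the hybrid
purity correlates with truth more strongly than either single-species
version — the acceptance script recomputes this comparison.

`fit_score_purity_curve()` maps scores to purity with a loess smooth fitted
to reference (score, purity) pairs (at least 20; degree 2, span 0.75 —
defaults chosen because the relationship is smooth, monotone and gently
curved, and verified on noise-free synthetic references to within 0.02).
Outside the reference score range, predictions extend linearly with the
boundary slope and are clamped to $[0,1]$. The packaged reference generator
draws pairs from a strictly decreasing cosine-of-affine curve; users with a
real patient-derived reference supply it as a two-column TSV in the same
schema.

## Cohort statistics

The cohort module reproduces the study designs used to characterise purity
as a model-intrinsic property: `within_between_differences()` compares
absolute purity differences of identical-passage sample pairs within versus
between models (two-sided Mann–Whitney U); `early_late_pairing()` pairs one
early- and one late-passage sample per model (seeded random choice among
ties, never the same sample twice) and reports Pearson correlation and a
paired t test; `balanced_strain_subset()` downsamples to equal per-cancer
counts in both host strains before `strain_comparison()`;
`cancer_purity_summary()` summarises per-cancer medians over cancers with at
least 20 samples; and `purity_mutation_correlation()` computes the Spearman
correlation (average-rank ties) between purity and somatic mutation count.
Exact Mann–Whitney p-values are used when both groups have at most 20
tie-free observations, the normal approximation otherwise.

On the packaged 19-model syngeneic table, `purity_mutation_correlation()`
gives $\rho \approx -0.03$ ($p \approx 0.91$): no detectable association
between purity and mutation burden.

## What the simulator does and does not emulate

The generators reproduce the statistical structure the estimators assume:
negative-binomial depth heterogeneity at SNP sites (the depth distribution
of RNA-seq SNPs is a modelling choice — mean 50, size 10 by default — since
only its heavy-tailed character matters to the cap), binomial read sampling
at fixed mixture fractions, binomial species counts per amplicon segment
with optional log-normal amplification bias, separable germline/somatic
annotation features, TPM-like log-normal expression with signature genes
scaling linearly in $(1-p)$ and a per-sample human/mouse split of the
stromal signal, and noisy monotone score–purity references.

They deliberately do **not** emulate: read-mapping reference bias (hence
somatic VAFs center at 0.5, not 0.47, unless `mapping_bias` is set),
copy-number alteration (which distorts VAF-based purity in aneuploid
genomes), spatial tumor heterogeneity, correlated expression between
signature genes, platform-specific score offsets, or alignment errors in
species assignment. Passing recovery tests on these simulations therefore
validates the estimators *under their own model assumptions*; accuracy on
real data additionally depends on how far those assumptions hold.

Default study conditions in the tests and acceptance script — 500 SNP sites
at mean depth 50; 108 segments at depth 3000; cohorts of 50–80 expression
samples with 2000 background genes and noise sd 0.2; 200 replicates for
recovery studies — mirror the designs the estimators were built for and keep
the full suite under a minute.

## Known limitations

* The syngeneic MLE assumes diploid, copy-neutral SNP sites and a single
  global $\theta$; subclonal structure or CNAs bias it.
* No confidence interval is reported beyond the returned likelihood profile.
* The hybrid score requires a reasonable ortholog map; genes without
  orthologs contribute human-only signal.
* Expression-based purity inherits the calibration reference: a curve
  fitted on one platform or species mix does not transfer automatically.
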