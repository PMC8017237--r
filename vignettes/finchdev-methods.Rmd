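---
title: "Methods: matched transcriptome–methylome analysis of a developing songbird telencephalon design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched transcriptome–methylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finchdev)
```

# The study design this package models

The package implements the statistical pipeline for a matched
transcriptome–methylome study of brain development: the same 24 samples —
4 ages (1, 20, 65 days post hatching, adult) × 2 sexes × 3 pooled
biological replicates — are assayed by RNA-seq (gene-level counts) and by
reduced-representation bisulfite sequencing in two flavors, conventional
RRBS (reading 5mC + 5hmC) and oxidative RRBS (reading 5mC only). Because
expression and methylation come from the same pools, per-gene expression
can be related directly to per-cytosine methylation. Birds have ZZ males
and ZW females with famously incomplete dosage compensation, so the sex
axis of the design doubles as a window on Z-chromosome dosage biology.

Every stage is exercised end-to-end on synthetic data with known ground
truth (the `simulate_*` generators), which is what the test suite and the
acceptance script measure recovery against.

# Differential expression

Counts are TMM-normalized (`normalize_counts`, via edgeR) and genes with
cpm < 1 in 22 or more of the 24 samples are removed
(`filter_low_expression`). The model is a negative-binomial GLM on the
8-level age × sex group factor with log effective library size as offset
and empirical-Bayes dispersion shrinkage toward a fitted mean–dispersion
trend.

Testing is stagewise (`fit_stagewise_de`). Five contrasts are of
interest: the *age* contrast — the average of the three later ages (both
sexes) minus 1 dph — and the male-minus-female contrast at each of the
four ages. A joint 5-d.f. likelihood-ratio omnibus test screens genes
with BH FDR across genes; only screened genes (FDR < 0.05) get stage-2
per-contrast tests, Holm-adjusted *within* each gene so that the
family-wise error rate is controlled per post-hoc family. Holm was chosen
for stage 2 because it is uniformly valid with no dependence assumptions;
any per-gene FWER procedure would fit the same slot.

# Developmental pattern classification

`classify_patterns` labels each later age H(igher), E(qual) or L(ower)
relative to 1 dph when the mean log-cpm difference (sexes pooled) exceeds
±1.65 per-gene standard deviations; under normality a null gene crosses a
one-sided 1.65 SD threshold about 5% of the time. The 3-letter codes over
{L,E,H} form a 27-element alphabet; 12 biologically interpretable codes
(change at exactly one time point, at the two middle points, from 20 dph
onwards, or from 65 dph onwards) form the selected subset
(`pattern_alphabet`).

The SD in the rule is the pooled within-group SD of log-cpm over the 8
design cells (16 residual d.f.). "SD per variable" is genuinely ambiguous
— per gene, per time point, or per cell — and we chose the pooled
within-group SD because it measures replicate noise without being
inflated by true age effects; `sd_method = "per_age"` gives the
two-age-only alternative. Zero-SD (constant) genes are forced to EEE and
flagged rather than producing 0/0.

# Differential methylation

Per-cytosine methylation is summarized as β = methylated/total reads and
M = log2((β + α)/(1 − β + α)) with offset α = 0.01
(`compute_m_values`). The offset bounds M at ±log2(1.01/0.01) ≈ ±6.66,
keeps the transform defined at β ∈ {0, 1}, and M is antisymmetric about
β = 0.5. Sites are kept when mean coverage ≥ 5× per sample *and* ≥ 6
methylated reads summed over samples (`filter_cytosines`); both
boundaries are closed (exactly 5.0 / exactly 6 pass).

`fit_moderated_dm` fits per-site least squares on the same 8-group
parameterization and the same five contrasts as expression, then shrinks
residual variances with the standard inverse-gamma empirical-Bayes
machinery (the moments fit via `limma::fitFDist`; the posterior-variance
combination is written out explicitly so the two limits are testable:
prior d.f. 0 recovers ordinary t statistics, infinite prior d.f. pins all
variances at the prior value). The omnibus is the moderated F over the
five contrasts with BH FDR; `subset_fdr` recomputes BH q-values when
attention is restricted to a subset of sites (e.g. CpGs in differentially
expressed genes), and recomputation on the full set reproduces the
original q-values exactly. CpG and CpH contexts run through the same code
path, distinguished only by their label. Sites are analyzed per strand
(no destranding) and complete-case per site, with a configurable
minimum-samples guard (default: all 24; the workflow scripts use 20 to
tolerate sporadic zero-coverage entries).

Hydroxymethylation is estimated per site and sample as
β(RRBS) − β(oxRRBS) (`subtract_hydroxymethylation`) — on the fraction
scale, because the two assays have different coverage, which makes raw
count subtraction ill-defined. Sampling noise drives some differences
negative; those are clipped to 0 and flagged, and the unclipped value is
kept alongside (the clipped mean is biased upward at low coverage, so
quantitative summaries should use the unclipped `raw`). 5hmC is reported
descriptively only — per-site counts are too shallow for a locus-wise
test.

Cytosines are annotated (`annotate_cytosines`) against promoter windows
(TSS − 2000 to TSS + 500, strand-oriented) with priority over gene
bodies; everything else is intergenic. All overlapping genes are
recorded, and only sites touching exactly one gene enter gene-level
integration.

# TFBS scanning and enrichment

The PWM scan (`scan_sequences`) is FIMO-like: the log2-odds of PWM versus
a 0-order background is summed per window on both strands, and a window
is a match when the exact p-value of its score — the probability of an
equal-or-higher score for a random background word — falls below 1e-4
(the FIMO default). Exactness comes from discretizing the log-odds to
1e-3-wide bins and convolving the per-column score distributions
(`pwm_score_distribution`); scanning uses the same integer matrix, so the
p-values are exact for the scored statistic, and the dynamic program is
validated against full 4^L enumeration for motifs up to length 8. The
background is estimated from the scanned sequences and symmetrized with
the reverse complement so both strands share one null distribution; hard
zeros in a PWM column are floored at 1e-10 before taking logs.
Windows containing N are skipped; a motif longer than the sequence
yields no matches rather than an error.

Enrichment (`motif_enrichment`) compares, per motif, the number of
sequences with ≥ 1 match in a foreground set against an outgroup with a
2×2 Pearson chi-squared (no continuity correction) and BH correction
across motifs. Binarizing per sequence keeps the chi-squared counting
unit independent; `unit = "matches"` switches to total match counts over
scanned windows. The direction is read from a log2 fold-change of hit
proportions with Haldane 0.5 correction. `cpg_flank_enrichment` applies
the same machinery to the 100-bp neighborhoods (50 bp each side,
truncated and flagged at chromosome ends) of differentially methylated
promoter cytosines versus non-DM promoter cytosines.

# Expression–methylation integration

`methylation_expression_mixed_model` regresses log-cpm per (gene, sample)
on the mean M-value of that gene's promoter (or genic) cytosines, with
random intercepts for gene and for sample, fit by REML (lme4/lmerTest).
Only uniquely annotated cytosines contribute; gene–sample cells with no
covered cytosine are dropped. The slope is reported with its
Satterthwaite-d.f. t-test p-value; singular fits are flagged, not hidden.
The estimate is invariant to adding a constant to all M-values and
equivariant under scaling, and collapses to pooled OLS when the
random-effect variances vanish.

`dm_in_de_enrichment` asks whether differentially methylated cytosines
concentrate in differentially expressed genes (2×2 chi-squared;
site-level counting by default, gene-level via `unit = "genes"` since the
natural counting unit is debatable), reports the percentage of DE genes
carrying ≥ 1 DM site per region class, and contrasts transcription
factors against other genes the same way.

# Dosage compensation

`mf_ratios` computes, per gene and age, mean male cpm over mean female
cpm (TMM-effective library sizes; ε = 1e-6 guards the denominator). A
ratio of 1 means complete compensation, 2 none. Unplaced "_random"
fragments merge into their parent chromosome class. The cutoff is the
95% linear-interpolation quantile (`stats::quantile` type 7) of the
autosomal ratio distribution — autosomes have no dosage effect, so their
upper tail calibrates "uncompensated". The cutoff is computed per age by
default (first and last age each get their own); a pooled mode exists
because the alternative reading is also defensible. Z genes are then
classed `from_birth` (below cutoff at both boundary ages), `acquired`
(at/above at first, below at last), `never` (at/above at both); the
fourth logical cell (compensated at birth, not in adulthood) falls
outside the scheme and is labeled `other`, and genes with zero expression
in both sexes at a boundary age are unclassifiable. By construction
roughly 5% of truly compensated genes exceed a 95% cutoff at any one age,
which bounds attainable classification accuracy.

`ratio_distribution` bins ratios into 1,000 equal-width bins as
percentages and overlays a loess smooth (span 0.1, locally linear — small
because at this bin resolution the distributions are narrow spikes; the
smooth conserves curve mass to within 1%). `dosage_group_stats` compares
mean log-cpm across the three classes by one-way ANOVA with Tukey HSD,
and `pairwise_fraction_tests` runs the 6 pairwise chi-squared tests of a
per-age fraction (e.g. the Z-linked share of sex-DE genes) with
Bonferroni ×6.

# The synthetic-data generator

`sim_config` fixes the study conditions: 24 samples in the 4×2×3 design;
negative-binomial counts (dispersion 0.05 — pooling three individuals per
sample absorbs inter-individual variance into this one knob) with
baseline log2-cpm uniform on 1–8; pattern effects expressed in units of
the within-group SD of log2 counts (default 3 SD) so the 1.65-SD
classifier has a controllable operating point; Z genes carrying a
male:female ratio of 2 throughout (`never`), 1 throughout
(`from_birth`), or log-linearly interpolated from 2 at day 1 to 1 at
adult (`acquired` — the trajectory shape is not pinned down by the data
the analysis emulates, so the simplest monotone interpolation was
chosen). Methylation counts are binomial over Poisson coverage (mean
20×), with a logit-scale age ramp at dm-flagged sites, lower CpH than
CpG baselines (means 0.05 vs 0.20), and oxRRBS success probabilities
scaled by (1 − hmc fraction), default 10%. Promoters are 2,500 nt
(matching the −2000/+500 window) of i.i.d. background (A/T 0.3, C/G 0.2)
with one exact consensus insertion per motif-positive gene. One global
seed determines everything; stages derive fixed child seeds (+1
annotation, +2 expression, +3 methylation, +4 promoters) so they can be
regenerated independently, and identical configs are bit-reproducible.

What the generator does *not* emulate: read-level artifacts (mapping
bias, bisulfite conversion error), correlated methylation along a
region, genuine mean–variance trends beyond a single NB dispersion,
overlap structure between neighboring genes, and any coupling between
expression and methylation in the default dataset (the coupled generator
`simulate_coupled_methylation_expression` exists precisely to plant a
known association for the mixed model). Passing recovery tests therefore
demonstrate that the estimators recover the truth *of this generative
model* at the stated effect sizes — not that real data meet those
assumptions.

# Numerical choices and problem sizes

Coordinates are 1-based inclusive throughout (the GRanges convention);
conversion to 0-based half-open happens exactly once, when writing
bedGraph. Non-significant sites with β = 0 are written as −0.001 so the
sign always encodes significance. log-cpm uses a library-size-scaled
prior count of 2. The mixed model uses lme4's default optimizer and
tolerances; the moderated-variance moments fit is `limma::fitFDist`.
The test and acceptance simulations use 1,000–4,000 genes and ~2,000–16,000
cytosines — sizes at which every Monte-Carlo assertion has comfortable
standard error while the whole suite runs in well under a minute per
stage; the workflow scripts under `analysis/` use 2,000 genes.

# Known limitations

Single-cytosine tests ignore spatial correlation (no region/DMR calling
or smoothing); quasi-likelihood F-tests and voom-style weights are out of
scope; W-linked genes are not simulated (the reference situation the
design mirrors lacks a W assembly); 5hmC gets no locus-wise test; GO
enrichment and ortholog mapping belong to external services and are not
reimplemented.
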