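# finchdev

Statistical pipeline for matched transcriptome–methylome studies of brain
development in birds: stagewise differential expression over an age × sex
design, developmental expression-pattern classification, RRBS/oxRRBS
differential methylation on M-values, transcription-factor binding-site
enrichment with exact PWM match p-values, expression–methylation
integration by linear mixed models, and Z-chromosome dosage-compensation
classification. Every stage is exercised end-to-end on synthetic data
with known ground truth, so estimator behavior (type-I error, power,
parameter recovery) is measurable.

The intended design is 24 samples — 4 ages (1, 20, 65 days post hatching,
adult) × 2 sexes × 3 pooled replicates — assayed by both RNA-seq and
(oxidative) reduced-representation bisulfite sequencing on the same
pools.

## The statistics at the core

* **Stagewise DE** — negative-binomial GLM on the 8 age × sex groups
  (TMM normalization, cpm ≥ 1 in ≥ 3 samples filter); a joint 5-d.f.
  likelihood-ratio omnibus over the contrasts of interest (age = mean of
  the later ages vs 1 dph; sex M−F at each age) screened at BH FDR <
  0.05, then per-contrast confirmation with Holm FWER control within each
  gene.
* **Pattern codes** — each later age labeled H/E/L against 1 dph at
  ±1.65 within-group SDs of log-cpm (≈ 5% one-sided null exceedance);
  27 possible codes, 12 selected trajectory groups.
* **Differential methylation** — β = meth/total,
  M = log2((β+α)/(1−β+α)) with α = 0.01; sites kept at mean coverage ≥ 5×
  and ≥ 6 methylated reads overall; per-site moderated F over the same
  five contrasts (empirical-Bayes variance shrinkage), BH FDR with
  subset recomputation; 5hmC = β(RRBS) − β(oxRRBS), clipped at 0 and
  flagged.
* **TFBS enrichment** — FIMO-style log-odds scan with *exact* match
  p-values from a dynamic program over a discretized score distribution
  (validated against 4^L enumeration), match threshold P < 1e-4; per-motif
  2×2 chi-squared (sequences with ≥ 1 hit, foreground vs outgroup), BH
  across motifs; same machinery on 100-bp flanks of differentially
  methylated promoter CpGs.
* **Integration** — log-cpm ~ mean promoter/genic M-value with gene and
  sample random intercepts (REML); chi-squared tests of DM-site
  concentration in DE genes and of TF vs non-TF differences.
* **Dosage compensation** — per-age male:female cpm ratios; cutoff =
  95% quantile of the autosomal ratio distribution; Z genes classed as
  compensated from birth / acquiring compensation / never compensated;
  1,000-bin ratio distributions with loess smoothing; ANOVA + Tukey
  across classes.

## Worked example

The numbered scripts under `analysis/` run the whole pipeline on a
simulated dataset (2,000 genes, 16,200 cytosines, 24 samples) written
under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_expression.R
Rscript analysis/03_patterns.R
Rscript analysis/04_methylation.R
Rscript analysis/05_tfbs.R
Rscript analysis/06_integration.R
Rscript analysis/07_dosage.R
```

Output of a run (abridged):

```
01: truth: 600 pattern genes, 152 Z-linked (from_birth=19, acquired=91, never=42),
    3322 dm sites, 600 motif-positive promoters
03: 621 of 2000 genes (31.1%) fall in the 12 selected pattern groups
    planted-pattern recovery: sensitivity 0.993, exact-code accuracy 0.963
04: 441 of 16167 sites differentially methylated (FDR < 0.05)
    mean 5hmC fraction estimate 0.0553 (unclipped 0.0192, truth 0.019)
05: top motif: planted (hit rate 0.96 vs 0.20, log2FC 2.29, q = 1.4e-222)
06: coupled simulation (true slope -0.040): estimate -0.0365 (SE 0.0027)
07: dosage classes (cutoff at q=0.95): class recovery accuracy 0.882
```

Reading the numbers: the pattern classifier finds 99% of genes planted
with 3-SD trajectory effects and assigns 96% their exact code; the
unclipped 5hmC estimate matches the simulated 10% hydroxymethylation of
a ~0.19 mean methylation level; the planted motif dominates its decoys;
and Z genes are assigned their true compensation class whenever their
M:F ratio is measured with adequate expression.

A cytosine report here is a long-format TSV
(`chrom pos strand context sample_id meth total`, 1-based positions);
counts are `gene_id` plus one column per sample; bedGraph output encodes
the methylation level as +β for significant and −max(β, 0.001) for
non-significant sites, so the sign always encodes the test outcome.

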