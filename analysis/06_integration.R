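#!/usr/bin/env Rscript
# Expression-methylation integration: (i) a linear mixed model of log-cpm
# on the per-gene mean promoter / genic M-value with gene and sample
# random intercepts, and (ii) chi-squared accounting of whether
# differentially methylated cytosines concentrate in differentially
# expressed genes, plus the TF vs non-TF contrast.

library(finchdev)

datadir <- file.path("results", "data")
design <- read_design(file.path(datadir, "design.tsv"))
genes <- read_annotation(file.path(datadir, "genes.gtf"))
lc <- read.delim(file.path("results", "logcpm.tsv"), check.names = FALSE)
logcpm <- as.matrix(lc[, design$sample_id]); rownames(logcpm) <- lc$gene_id
de <- read.delim(file.path("results", "de.tsv"))
dm <- read.delim(file.path("results", "dm.tsv"))

rrbs <- read_cytosine_report(file.path(datadir, "rrbs.tsv"), design, "rrbs")
filt <- filter_cytosines(rrbs)
bm <- compute_m_values(filt)
keep <- match(dm$site, rownames(bm$M))
M <- bm$M[keep, , drop = FALSE]
annot <- dm[, c("annotation", "gene_ids", "gene_id", "unique_gene")]
message(sprintf("%.1f%% of sites have a unique gene annotation",
                100 * mean(annot$unique_gene)))

age_genes <- de$gene_id[de$omnibus_fdr < 0.05 & !is.na(de$holm_age) &
                          de$holm_age < 0.05]
rows <- list()
for (rc in c("promoter", "genic")) {
  fit <- methylation_expression_mixed_model(logcpm, M, annot, rc,
                                            genes = age_genes)
  message(sprintf("%s: slope %.4f (SE %.4f, p = %.2g; %d genes)",
                  rc, fit$slope, fit$se, fit$p, fit$n_genes))
  rows[[rc]] <- data.frame(region_class = rc, slope = fit$slope, se = fit$se,
                           p = fit$p, n_genes = fit$n_genes,
                           n_obs = fit$n_obs, singular = fit$singular)
}
write.table(do.call(rbind, rows), file.path("results", "association.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# in the default dataset expression and methylation are generated
# independently, so the slopes above are null checks; recover a planted
# association from the coupled generator to show the estimator working
cp <- simulate_coupled_methylation_expression(500, design, slope = -0.04,
                                              seed = 20210319)
cfit <- methylation_expression_mixed_model(cp$logcpm, cp$M, cp$site_annot)
message(sprintf("coupled simulation (true slope -0.040): estimate %.4f (SE %.4f, p = %.2g)",
                cfit$slope, cfit$se, cfit$p))

universe <- intersect(de$gene_id, unique(annot$gene_id[annot$unique_gene]))
tf_flag <- setNames(genes$is_tf, genes$gene_id)
enr <- dm_in_de_enrichment(annot, dm$omnibus_fdr < 0.05, age_genes, universe,
                           tf_flag = tf_flag)
message(sprintf("DM-in-DE chi2 = %.2f (p = %.2g); DE genes with >=1 DM site: promoter %.1f%%, genic %.1f%%",
                enr$dm_in_de$chi2, enr$dm_in_de$p,
                enr$pct_de_with_dm["promoter"], enr$pct_de_with_dm["genic"]))
if (!is.null(enr$tf))
  message(sprintf("TF vs non-TF DM-gene fractions: %.1f%% vs %.1f%% (chi2 p = %.2g)",
                  enr$tf$pct_tf, enr$tf$pct_nontf, enr$tf$p))
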