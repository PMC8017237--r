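#!/usr/bin/env Rscript
# Dosage compensation: male:female cpm ratios per age, the autosomal
# 95%-quantile cutoff, three-way classification of Z genes, the binned
# ratio distribution with loess smoothing, and ANOVA (Tukey post hoc) of
# mean expression across dosage classes.

library(finchdev)

datadir <- file.path("results", "data")
design <- read_design(file.path(datadir, "design.tsv"))
dge <- read_counts(file.path(datadir, "counts.tsv"), design)
dge <- normalize_counts(dge)
genes <- read_annotation(file.path(datadir, "genes.gtf"))

ratios <- mf_ratios(dge, design, genes)
zbar <- colMeans(ratios[ratios$chrom_class == "Z",
                        paste0("ratio_", levels(design$age))], na.rm = TRUE)
message(sprintf("mean Z-gene M:F ratio by age: %s",
                paste(levels(design$age), sprintf("%.2f", zbar),
                      sep = "=", collapse = ", ")))

cl <- classify_dosage(ratios)
print(cl)
write.table(cbind(cl$table,
                  cutoff_first = cl$cutoff[[1]], cutoff_last = cl$cutoff[[2]]),
            file.path("results", "dosage.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(datadir, "truth_expression.tsv"))
tr <- truth$dosage_class[match(cl$table$gene_id, truth$gene_id)]
message(sprintf("class recovery accuracy: %.3f",
                mean(cl$table$class == tr, na.rm = TRUE)))

rd <- ratio_distribution(ratios$ratio_adult, ratios$chrom_class)
write.table(rd, file.path("results", "ratio_distribution_adult.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

lc <- read.delim(file.path("results", "logcpm.tsv"), check.names = FALSE)
logcpm <- as.matrix(lc[, design$sample_id]); rownames(logcpm) <- lc$gene_id
gs <- tryCatch(dosage_group_stats(logcpm, cl), error = function(e) NULL)
if (!is.null(gs)) {
  message(sprintf("ANOVA across dosage classes: F = %.2f, p = %.2g", gs$F, gs$p))
  print(gs$tukey)
}
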