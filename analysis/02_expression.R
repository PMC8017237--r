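#!/usr/bin/env Rscript
# Differential expression: TMM normalization, low-expression filtering, and
# the stagewise omnibus + per-contrast testing scheme (age effect averaged
# over the three later ages vs 1 dph; sex effect at each age).

library(finchdev)

datadir <- file.path("results", "data")
design <- read_design(file.path(datadir, "design.tsv"))
dge <- read_counts(file.path(datadir, "counts.tsv"), design)

dge <- filter_low_expression(dge)
message(sprintf("%d genes pass the low-expression filter", nrow(dge)))
dge <- normalize_counts(dge)

de <- fit_stagewise_de(dge, design)
write.table(de$table, file.path("results", "de.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

logcpm <- log_cpm(dge)
write.table(data.frame(gene_id = rownames(logcpm), logcpm, check.names = FALSE),
            file.path("results", "logcpm.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

age_genes <- significant_genes(de, "age")
sex_genes <- unique(unlist(lapply(paste0("sex_", levels(design$age)),
                                  function(ct) significant_genes(de, ct))))
message(sprintf("age effect: %d of %d genes (%.1f%%) significant (stagewise, FDR<0.05 + Holm<0.05)",
                length(age_genes), nrow(dge), 100 * length(age_genes) / nrow(dge)))
message(sprintf("sex effect at >=1 age: %d genes (%.1f%%)",
                length(sex_genes), 100 * length(sex_genes) / nrow(dge)))

truth <- read.delim(file.path(datadir, "truth_expression.tsv"))
planted <- truth$gene_id[truth$pattern != "EEE"]
message(sprintf("of %d genes with a planted age pattern, %d (%.1f%%) are age-significant",
                length(planted), sum(planted %in% age_genes),
                100 * mean(planted %in% age_genes)))
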