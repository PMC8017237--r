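#!/usr/bin/env Rscript
# Developmental expression-pattern classification: each gene's log-cpm at
# 20 dph, 65 dph and adult is called Higher/Equal/Lower relative to 1 dph
# using the 1.65-SD rule, and genes are grouped into the 12 selected
# trajectory codes.

library(finchdev)

design <- read_design(file.path("results", "data", "design.tsv"))
lc <- read.delim(file.path("results", "logcpm.tsv"), check.names = FALSE)
logcpm <- as.matrix(lc[, design$sample_id])
rownames(logcpm) <- lc$gene_id

pat <- classify_patterns(logcpm, design)
write.table(pat, file.path("results", "patterns.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sel <- pat[pat$selected, ]
counts <- sort(table(sel$code), decreasing = TRUE)
message(sprintf("%d of %d genes (%.1f%%) fall in the 12 selected pattern groups:",
                nrow(sel), nrow(pat), 100 * nrow(sel) / nrow(pat)))
message(paste(names(counts), counts, sep = "=", collapse = ", "))

truth <- read.delim(file.path("results", "data", "truth_expression.tsv"))
tr <- truth$pattern[match(pat$gene_id, truth$gene_id)]
planted <- tr != "EEE"
message(sprintf("planted-pattern recovery: sensitivity %.3f, exact-code accuracy %.3f",
                mean(pat$code[planted] != "EEE"),
                mean(pat$code[planted] == tr[planted])))
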