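#!/usr/bin/env Rscript
# TFBS enrichment: promoters of genes in the selected developmental pattern
# groups are scanned against an outgroup of pattern-free genes, per motif,
# with FIMO-style exact match p-values (P < 1e-4) and a chi-squared 2x2
# test per motif, BH-corrected.

library(finchdev)

datadir <- file.path("results", "data")
prom <- as.character(Biostrings::readDNAStringSet(file.path(datadir, "promoters.fa")))
names(prom) <- sub("\\s.*", "", names(prom))
pat <- read.delim(file.path("results", "patterns.tsv"))

motif <- make_pwm("planted", matrix(c(9, 0, 0, 0, 0, 9, 0, 0, 0, 0, 9, 0,
                                      0, 0, 0, 9, 9, 0, 0, 0, 0, 9, 0, 0,
                                      0, 0, 9, 0, 0, 0, 0, 9), 4),
                  pseudocount = 0.5)
set.seed(1)
decoys <- lapply(1:5, function(i)
  make_pwm(paste0("decoy", i), matrix(rgamma(4 * 8, 2), 4), pseudocount = 0.3))

fg_genes <- pat$gene_id[pat$selected]
bg_genes <- setdiff(pat$gene_id, fg_genes)
enr <- motif_enrichment(prom[fg_genes], prom[bg_genes], c(list(motif), decoys))
write.table(enr, file.path("results", "tfbs_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("scanned %d foreground vs %d outgroup promoters with %d motifs",
                length(fg_genes), length(bg_genes), nrow(enr)))
top <- enr[order(enr$q), ][1, ]
message(sprintf("top motif: %s (hit rate %.2f vs %.2f, log2FC %.2f, q = %.2g)",
                top$motif_id, top$fg_hits / top$fg_total,
                top$bg_hits / top$bg_total, top$log2fc, top$q))
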