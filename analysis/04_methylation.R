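#!/usr/bin/env Rscript
# Differential methylation: beta/M-values with the 0.01 offset, the
# coverage (mean >= 5x) and methylated-read (>= 6 summed) filters, a
# moderated-variance fit of the same five contrasts as the expression
# analysis, hydroxymethylation by RRBS - oxRRBS subtraction, genomic
# annotation of cytosines, and the signed-significance bedGraph track.

library(finchdev)

datadir <- file.path("results", "data")
design <- read_design(file.path(datadir, "design.tsv"))
rrbs <- read_cytosine_report(file.path(datadir, "rrbs.tsv"), design, "rrbs")
oxrrbs <- read_cytosine_report(file.path(datadir, "oxrrbs.tsv"), design, "oxrrbs")
genes <- read_annotation(file.path(datadir, "genes.gtf"))

filt <- filter_cytosines(rrbs)
message(sprintf("%d of %d sites pass the coverage/methylation filters",
                nrow(filt$sites), nrow(rrbs$sites)))
bm <- compute_m_values(filt)
dm <- fit_moderated_dm(bm$M, design, min_samples = 20)
annot <- annotate_cytosines(subset_meth(filt, dm$kept), genes)

out <- cbind(dm$table, annot)
write.table(out, file.path("results", "dm.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
sig <- out$omnibus_fdr < 0.05
message(sprintf("%d of %d sites differentially methylated (FDR < 0.05); %s",
                sum(sig), nrow(out),
                paste(names(table(out$annotation[sig])),
                      table(out$annotation[sig]), sep = "=", collapse = ", ")))

# hydroxymethylation is reported descriptively only: per-site counts are too
# shallow for a locus-wise 5hmC test
h <- subtract_hydroxymethylation(rrbs, oxrrbs)
message(sprintf("mean 5hmC fraction estimate %.4f (unclipped %.4f; %.1f%% of entries clipped at 0)",
                mean(h$hmc, na.rm = TRUE), mean(h$raw, na.rm = TRUE),
                100 * mean(h$clipped, na.rm = TRUE)))

beta_kept <- bm$beta[dm$kept, , drop = FALSE]
sites_kept <- filt$sites[dm$kept, , drop = FALSE]
write_methylation_bedgraph(
  data.frame(chrom = sites_kept$chrom, pos = sites_kept$pos,
             beta = rowMeans(beta_kept, na.rm = TRUE), significant = sig),
  file.path("results", "dm.bedGraph"))
message("wrote results/dm.tsv and results/dm.bedGraph")
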