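#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a 4-age x 2-sex x 3-pool design with
# negative-binomial expression counts, RRBS/oxRRBS methylation counts, gene
# annotation, promoter sequences with a planted motif, and ground-truth
# labels. Everything downstream (02-07) consumes these files.

library(finchdev)

outdir <- file.path("results", "data")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

design <- sample_design()
motif <- make_pwm("planted", matrix(c(9, 0, 0, 0, 0, 9, 0, 0, 0, 0, 9, 0,
                                      0, 0, 0, 9, 9, 0, 0, 0, 0, 9, 0, 0,
                                      0, 0, 9, 0, 0, 0, 0, 9), 4),
                  pseudocount = 0.5)
cfg <- sim_config(n_genes = 2000, seed = 20210319, planted_motif = motif,
                  baseline_logcpm_range = c(2, 8))

ann <- simulate_annotation(cfg)
expr <- simulate_expression(cfg, design, ann)
meth <- simulate_methylation(cfg, design, ann)
# plant the motif in the promoters of genes with an age pattern (so the
# TFBS stage has a true enrichment signal among developmentally dynamic genes)
positive <- expr$truth$gene_id[expr$truth$pattern != "EEE"]
prom <- simulate_promoters(cfg, ann, positive_genes = positive)

write_design(design, file.path(outdir, "design.tsv"))
write_counts(expr$counts, file.path(outdir, "counts.tsv"))
write_cytosine_report(meth$rrbs, file.path(outdir, "rrbs.tsv"))
write_cytosine_report(meth$oxrrbs, file.path(outdir, "oxrrbs.tsv"))
write_annotation_gtf(ann, file.path(outdir, "genes.gtf"))
Biostrings::writeXStringSet(Biostrings::DNAStringSet(prom$seqs),
                            file.path(outdir, "promoters.fa"))
write.table(expr$truth, file.path(outdir, "truth_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(meth$truth, file.path(outdir, "truth_methylation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = names(prom$truth), planted = prom$truth),
            file.path(outdir, "truth_motif.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("wrote %d genes x %d samples, %d cytosines (rrbs+oxrrbs), %d promoters to %s",
                nrow(expr$counts), ncol(expr$counts), nrow(meth$rrbs$sites),
                length(prom$seqs), outdir))
message(sprintf("truth: %d pattern genes, %d Z-linked (%s), %d dm sites, %d motif-positive promoters",
                sum(expr$truth$pattern != "EEE"),
                sum(expr$truth$dosage_class != "autosomal_null"),
                paste(names(table(expr$truth$dosage_class)[c("from_birth", "acquired", "never")]),
                      table(expr$truth$dosage_class)[c("from_birth", "acquired", "never")],
                      sep = "=", collapse = ", "),
                sum(meth$truth$dm_flag), sum(prom$truth)))
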