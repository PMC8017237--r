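#' Mixed-model association between methylation and expression
#'
#' Models log-cpm per (gene, sample) as a linear function of the mean
#' M-value of the gene's cytosines in a region class (promoter or genic),
#' with random intercepts for gene and for sample (REML). Only cytosines
#' with a unique gene annotation contribute; gene-sample cells without a
#' covered cytosine are dropped (complete case). The returned slope has
#' units of log2-cpm per M-value unit; a negative slope means higher
#' methylation goes with lower expression.
#'
#' @param logcpm Genes x samples log-cpm matrix.
#' @param M Sites x samples M-value matrix.
#' @param site_annot Annotation per site (rows aligned to M) as from
#'   \code{annotate_cytosines}: columns annotation, gene_id, unique_gene.
#' @param region_class "promoter" or "genic".
#' @param genes Optional character vector restricting the gene universe
#'   (e.g. differentially expressed genes).
#' @return list of class \code{assoc_fit}: slope, se, df, p (Satterthwaite),
#'   n_genes, n_samples, n_obs, singular (logical), model (the lmerMod).
#' @export
methylation_expression_mixed_model <- function(logcpm, M, site_annot,
                                               region_class = c("promoter", "genic"),
                                               genes = NULL) {
  region_class <- match.arg(region_class)
  stopifnot(nrow(site_annot) == nrow(M), ncol(M) == ncol(logcpm))
  use <- site_annot$annotation == region_class & site_annot$unique_gene &
    !is.na(site_annot$gene_id) & site_annot$gene_id %in% rownames(logcpm)
  if (!is.null(genes)) use <- use & site_annot$gene_id %in% genes
  if (!any(use)) stop("no usable cytosines for region class ", region_class)
  Msub <- M[use, , drop = FALSE]
  gene_of <- site_annot$gene_id[use]
  # per-(gene, sample) mean M over the gene's region-class cytosines
  meanM <- rowsum(Msub, gene_of, na.rm = TRUE) /
    rowsum((!is.na(Msub)) * 1, gene_of)
  ug <- rownames(meanM)
  if (length(ug) < 2) stop("fewer than 2 genes with usable cytosines")
  df <- data.frame(
    expr = as.vector(logcpm[ug, , drop = FALSE]),
    M = as.vector(meanM),
    gene = rep(ug, times = ncol(M)),
    sample = rep(colnames(M), each = length(ug)))
  df <- df[is.finite(df$M) & is.finite(df$expr), ]
  if (length(unique(df$sample)) < 2) stop("fewer than 2 samples with data")
  if (stats::var(df$M) == 0) stop("M-value covariate is constant")
  fit <- lmerTest::lmer(expr ~ M + (1 | gene) + (1 | sample), data = df,
                        REML = TRUE)
  co <- stats::coef(summary(fit))["M", ]
  structure(list(slope = unname(co["Estimate"]), se = unname(co["Std. Error"]),
                 df = unname(co["df"]), p = unname(co["Pr(>|t|)"]),
                 n_genes = length(unique(df$gene)),
                 n_samples = length(unique(df$sample)), n_obs = nrow(df),
                 singular = lme4::isSingular(fit), model = fit),
            class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("mixed-model slope %.4f (SE %.4f, p = %.3g; %d genes x %d samples)%s\n",
              x$slope, x$se, x$p, x$n_genes, x$n_samples,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Pearson chi-squared on a 2x2 table
#'
#' No continuity correction. Returns NA with a note when a margin is zero.
#'
#' @param tab 2x2 integer matrix.
#' @return list: chi2, p, note.
#' @keywords internal
chi2_2x2 <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(chi2 = NA_real_, p = NA_real_,
                note = "zero margin: chi-squared undefined"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value, note = NA_character_)
}

#' Is differential methylation enriched in differentially expressed genes?
#'
#' Builds, over the harmonized gene universe (genes with both expression
#' and methylation coverage), (i) a chi-squared test of the distribution of
#' DM cytosines across DE vs non-DE genes (site-level by default, gene-level
#' optional), (ii) the percentage of DE genes carrying at least one DM
#' cytosine per region class, and (iii) a TF vs non-TF chi-squared among DE
#' genes on carrying a DM cytosine.
#'
#' @param site_annot Site annotation (annotation, gene_id, unique_gene).
#' @param dm_flag Logical per site: differentially methylated.
#' @param de_genes Character vector of differentially expressed gene ids.
#' @param universe Character vector: all genes with both data types.
#' @param tf_flag Named logical vector (by gene id), TRUE for transcription
#'   factors; optional.
#' @param unit "sites" (default) or "genes" for the DM-in-DE test.
#' @return list of class \code{dm_de_enrichment}: dm_in_de (chi2, p, table),
#'   pct_de_with_dm (named by region class), n_de, tf (chi2, p, pct_tf,
#'   pct_nontf) or NULL.
#' @export
dm_in_de_enrichment <- function(site_annot, dm_flag, de_genes, universe,
                                tf_flag = NULL, unit = c("sites", "genes")) {
  unit <- match.arg(unit)
  stopifnot(length(dm_flag) == nrow(site_annot))
  if (!length(universe)) stop("empty gene universe")
  de_genes <- intersect(de_genes, universe)
  keep <- site_annot$unique_gene & !is.na(site_annot$gene_id) &
    site_annot$gene_id %in% universe & site_annot$annotation != "intergenic"
  sa <- site_annot[keep, , drop = FALSE]
  dm <- dm_flag[keep]
  in_de <- sa$gene_id %in% de_genes

  if (unit == "sites") {
    tab <- rbind(de = c(dm = sum(dm & in_de), not_dm = sum(!dm & in_de)),
                 non_de = c(sum(dm & !in_de), sum(!dm & !in_de)))
  } else {
    has_dm <- tapply(dm, sa$gene_id, any)
    g_de <- names(has_dm) %in% de_genes
    tab <- rbind(de = c(dm = sum(has_dm[g_de]), not_dm = sum(!has_dm[g_de])),
                 non_de = c(sum(has_dm[!g_de]), sum(!has_dm[!g_de])))
  }
  test <- chi2_2x2(tab)

  pct <- vapply(c(promoter = "promoter", genic = "genic"), function(rc) {
    g <- unique(sa$gene_id[sa$annotation == rc & sa$gene_id %in% de_genes])
    if (!length(g)) return(0)
    gdm <- unique(sa$gene_id[sa$annotation == rc & dm])
    100 * mean(g %in% gdm)
  }, numeric(1))

  tf <- NULL
  if (!is.null(tf_flag)) {
    has_dm_gene <- unique(sa$gene_id[dm])
    de_tf <- de_genes[tf_flag[de_genes] %in% TRUE]
    de_ntf <- setdiff(de_genes, de_tf)
    tab_tf <- rbind(tf = c(dm = sum(de_tf %in% has_dm_gene),
                           no_dm = sum(!de_tf %in% has_dm_gene)),
                    non_tf = c(sum(de_ntf %in% has_dm_gene),
                               sum(!de_ntf %in% has_dm_gene)))
    tt <- chi2_2x2(tab_tf)
    tf <- list(chi2 = tt$chi2, p = tt$p, table = tab_tf,
               pct_tf = if (length(de_tf)) 100 * mean(de_tf %in% has_dm_gene) else NA_real_,
               pct_nontf = if (length(de_ntf)) 100 * mean(de_ntf %in% has_dm_gene) else NA_real_)
  }
  structure(list(dm_in_de = list(chi2 = test$chi2, p = test$p, table = tab,
                                 note = test$note),
                 pct_de_with_dm = pct, n_de = length(de_genes),
                 n_universe = length(universe), unit = unit, tf = tf),
            class = "dm_de_enrichment")
}
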