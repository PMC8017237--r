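#' Beta- and M-values from methylation counts
#'
#' beta = methylated/total reads; M = log2((beta + alpha)/(1 - beta + alpha))
#' with offset alpha (default 0.01). The offset bounds M at
#' +/- log2((1 + alpha)/alpha) and makes the transform defined at beta = 0
#' and 1; M is antisymmetric about beta = 0.5. Entries with total = 0 are NA.
#'
#' @param m A \code{meth_mat}, or a list with \code{meth} and \code{total}
#'   matrices.
#' @param alpha Offset (default 0.01).
#' @return list with \code{beta} and \code{M} matrices.
#' @export
compute_m_values <- function(m, alpha = 0.01) {
  stopifnot(alpha > 0)
  beta <- m$meth / ifelse(m$total > 0, m$total, NA_real_)
  M <- log2((beta + alpha) / (1 - beta + alpha))
  list(beta = beta, M = M)
}

#' Quality filter for cytosine sites
#'
#' Retains a site iff (i) its mean total coverage across samples is at least
#' \code{min_mean_coverage} and (ii) its methylated reads summed over all
#' samples reach \code{min_total_meth}.
#'
#' @param m A \code{meth_mat}.
#' @param min_mean_coverage Minimal average per-sample coverage (default 5).
#' @param min_total_meth Minimal summed methylated reads (default 6).
#' @return The filtered \code{meth_mat}.
#' @export
filter_cytosines <- function(m, min_mean_coverage = 5, min_total_meth = 6L) {
  keep <- rowMeans(m$total) >= min_mean_coverage &
    rowSums(m$meth) >= min_total_meth
  subset_meth(m, keep)
}

#' Subset a meth_mat by site
#'
#' @param m A \code{meth_mat}.
#' @param i Logical or integer site index.
#' @return The subsetted \code{meth_mat}.
#' @export
subset_meth <- function(m, i) {
  meth_matrix(m$sites[i, , drop = FALSE], m$meth[i, , drop = FALSE],
              m$total[i, , drop = FALSE], m$assay)
}

#' Moderated differential methylation on M-values
#'
#' Per-site ordinary least squares on the 8-level age x sex group factor,
#' with residual variances shrunk toward an inverse-gamma prior fitted by
#' moments on the observed variances (the standard moderated-t machinery),
#' giving augmented degrees of freedom. Tests the same five contrasts as
#' the expression analysis: a joint moderated F omnibus with BH FDR across
#' sites, plus per-contrast moderated t.
#'
#' @param M Sites x samples M-value matrix (complete cases only are used;
#'   sites with fewer than \code{min_samples} finite values are dropped).
#' @param design A \code{sample_design}.
#' @param prior_df NULL (default) to estimate the prior degrees of freedom
#'   from the data; a number to fix it (0 recovers ordinary least-squares t).
#' @param min_samples Minimal finite observations per retained site
#'   (default: all samples).
#' @return A list of class \code{dm_result}: \code{table} (site, per-contrast
#'   logFC/t/p, F, omnibus_p, omnibus_fdr), \code{s2}, \code{s2_post},
#'   \code{df_prior}, \code{df_residual}, \code{kept} (row index into M).
#' @export
fit_moderated_dm <- function(M, design, prior_df = NULL,
                             min_samples = nrow(design)) {
  stopifnot(ncol(M) == nrow(design))
  kept <- which(rowSums(is.finite(M)) >= min_samples)
  if (!length(kept)) stop("no site passes the complete-case guard")
  M <- M[kept, , drop = FALSE]
  mm <- stats::model.matrix(~0 + group, data = design)
  colnames(mm) <- levels(design$group)
  fit <- limma::lmFit(M, mm)
  C <- study_contrasts(design)
  cfit <- limma::contrasts.fit(fit, C)
  s2 <- cfit$sigma^2
  df <- cfit$df.residual
  if (any(df <= 0)) stop("site with zero residual degrees of freedom")
  if (is.null(prior_df)) {
    fd <- limma::fitFDist(s2, df)
    d0 <- fd$df2
    s02 <- fd$scale
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2) else 0
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + df * s2) / (d0 + df)
  tstat <- cfit$coefficients / (cfit$stdev.unscaled * sqrt(s2_post))
  df_total <- df + d0
  p_t <- 2 * stats::pt(-abs(tstat), df_total)
  tobj <- cfit
  tobj$t <- tstat
  Fstat <- limma::classifyTestsF(tobj, fstat.only = TRUE)
  df1 <- attr(Fstat, "df1")
  omnibus_p <- stats::pf(as.numeric(Fstat), df1, df_total, lower.tail = FALSE)
  tab <- data.frame(site = rownames(M),
                    cfit$coefficients, tstat, p_t,
                    F = as.numeric(Fstat), omnibus_p = omnibus_p,
                    omnibus_fdr = stats::p.adjust(omnibus_p, "BH"),
                    row.names = rownames(M), check.names = FALSE)
  nc <- colnames(C)
  colnames(tab)[1 + seq_along(nc)] <- paste0("logFC_", nc)
  colnames(tab)[1 + length(nc) + seq_along(nc)] <- paste0("t_", nc)
  colnames(tab)[1 + 2 * length(nc) + seq_along(nc)] <- paste0("p_", nc)
  structure(list(table = tab, contrasts = C, s2 = s2, s2_post = s2_post,
                 df_prior = d0, df_residual = df, kept = kept),
            class = "dm_result")
}

#' Recompute BH FDR on a subset of sites
#'
#' When attention is restricted to a subset (e.g. CpGs in differentially
#' expressed genes) the FDR is recalculated over that subset's raw omnibus
#' p-values rather than carried over from the full analysis.
#'
#' @param dm A \code{dm_result} (or any data.frame with an
#'   \code{omnibus_p} column via \code{dm$table}).
#' @param subset Logical or integer index into the rows of \code{dm$table}.
#' @return Numeric vector of subset BH q-values, named by site.
#' @export
subset_fdr <- function(dm, subset) {
  p <- dm$table$omnibus_p[subset]
  stats::setNames(stats::p.adjust(p, "BH"), dm$table$site[subset])
}

#' Hydroxymethylation by RRBS minus oxRRBS subtraction
#'
#' Conventional RRBS reads 5mC + 5hmC; oxidative RRBS reads 5mC only. The
#' per-site, per-sample 5hmC fraction is estimated as
#' beta_rrbs - beta_oxrrbs on the methylation-fraction scale (coverage
#' differs between assays, so count subtraction is ill-defined); sampling
#' noise can drive the difference negative, in which case it is clipped to
#' 0 and flagged.
#'
#' @param rrbs,oxrrbs \code{meth_mat} objects for the two assays.
#' @return list: \code{sites} (matched site table), \code{hmc} (clipped
#'   estimates), \code{raw} (unclipped differences), \code{clipped} (logical
#'   matrix), \code{n_unmatched} (sites present in only one assay, dropped).
#' @export
subtract_hydroxymethylation <- function(rrbs, oxrrbs) {
  k1 <- site_key(rrbs$sites)
  k2 <- site_key(oxrrbs$sites)
  common <- intersect(k1, k2)
  if (!length(common)) stop("no overlapping sites between rrbs and oxrrbs")
  i1 <- match(common, k1)
  i2 <- match(common, k2)
  b1 <- compute_m_values(subset_meth(rrbs, i1))$beta
  b2 <- compute_m_values(subset_meth(oxrrbs, i2))$beta
  raw <- b1 - b2
  hmc <- pmax(raw, 0)
  list(sites = rrbs$sites[i1, , drop = FALSE], hmc = hmc, raw = raw,
       clipped = !is.na(raw) & raw < 0,
       n_unmatched = (length(k1) - length(common)) + (length(k2) - length(common)))
}

#' Annotate cytosines relative to genes
#'
#' A site falling in any promoter window (TSS - \code{promoter_up} to
#' TSS + \code{promoter_down}, strand-oriented) is "promoter" (priority over
#' gene bodies); otherwise a site inside any gene body is "genic"; all
#' others are "intergenic". All overlapping gene ids are recorded and a
#' unique-gene flag marks sites touching exactly one gene.
#'
#' @param sites data.frame with chrom, pos (1-based), or a \code{meth_mat}.
#' @param genes Annotation data.frame (see \code{read_annotation}).
#' @param promoter_up,promoter_down Promoter window, nt up/downstream of the
#'   TSS (defaults 2000 / 500).
#' @return data.frame aligned to sites: annotation, gene_ids
#'   (comma-separated), gene_id (set when unique), unique_gene.
#' @export
annotate_cytosines <- function(sites, genes, promoter_up = 2000L,
                               promoter_down = 500L) {
  stopifnot(promoter_up >= 0, promoter_down >= 0)
  if (inherits(sites, "meth_mat")) sites <- sites$sites
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, width = 1))
  prom_start <- ifelse(genes$strand == "+", genes$tss - promoter_up,
                       genes$tss - promoter_down)
  prom_end <- ifelse(genes$strand == "+", genes$tss + promoter_down,
                     genes$tss + promoter_up)
  prom_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(pmax(prom_start, 1L), prom_end))
  body_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hp <- GenomicRanges::findOverlaps(site_gr, prom_gr)
  hb <- GenomicRanges::findOverlaps(site_gr, body_gr)
  n <- nrow(sites)
  in_prom <- tabulate(S4Vectors::queryHits(hp), n) > 0
  in_body <- tabulate(S4Vectors::queryHits(hb), n) > 0
  annotation <- ifelse(in_prom, "promoter", ifelse(in_body, "genic", "intergenic"))
  gl <- vector("list", n)
  for (h in list(hp, hb)) {
    q <- S4Vectors::queryHits(h)
    s <- S4Vectors::subjectHits(h)
    if (length(q)) {
      sp <- split(genes$gene_id[s], q)
      idx <- as.integer(names(sp))
      gl[idx] <- Map(c, gl[idx], sp)
    }
  }
  gl <- lapply(gl, function(g) sort(unique(g)))
  n_genes <- lengths(gl)
  data.frame(annotation = annotation,
             gene_ids = vapply(gl, paste, "", collapse = ","),
             gene_id = ifelse(n_genes == 1, vapply(gl, function(g)
               if (length(g)) g[1] else NA_character_, ""), NA_character_),
             unique_gene = n_genes == 1,
             row.names = rownames(sites))
}
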