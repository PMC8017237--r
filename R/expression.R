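#' TMM normalization
#'
#' Computes trimmed-mean-of-M-values scaling factors (30% M-trim, 5% A-trim,
#' precision weighting, factors rescaled to geometric mean 1) so that
#' effective library size = lib.size x norm factor.
#'
#' @param dge A \code{DGEList} (e.g. from \code{read_counts}).
#' @return The \code{DGEList} with \code{samples$norm.factors} set.
#' @export
normalize_counts <- function(dge) {
  if (ncol(dge) < 2) stop("need at least 2 samples for TMM")
  if (any(dge$samples$lib.size == 0)) stop("sample with zero library size")
  edgeR::calcNormFactors(dge, method = "TMM")
}

#' log2 counts-per-million
#'
#' @param dge A \code{DGEList} (normalized or not).
#' @param prior_count Library-size-scaled prior count added to stabilize
#'   low counts (default 2).
#' @return Matrix of log2-cpm values, genes x samples.
#' @export
log_cpm <- function(dge, prior_count = 2) {
  edgeR::cpm(dge, log = TRUE, prior.count = prior_count)
}

#' Filter genes with very low expression
#'
#' A gene is removed when its cpm falls below \code{min_cpm} in more than
#' \code{max_low_samples} samples — with the defaults and 24 samples: cpm < 1
#' in 22 or more samples.
#'
#' @param dge A \code{DGEList}.
#' @param min_cpm cpm threshold (default 1).
#' @param max_low_samples Maximum tolerated number of below-threshold
#'   samples (default 21).
#' @return The filtered \code{DGEList} (library sizes kept).
#' @export
filter_low_expression <- function(dge, min_cpm = 1, max_low_samples = 21L) {
  if (!nrow(dge)) return(dge)
  low <- rowSums(edgeR::cpm(dge) < min_cpm)
  dge[low <= max_low_samples, , keep.lib.sizes = TRUE]
}

#' Contrast matrix for the study's five contrasts
#'
#' Age: the average of the three later ages (both sexes) minus the first
#' age (both sexes). Sex: male minus female at each age separately.
#'
#' @param design A \code{sample_design}.
#' @return Groups x 5 contrast matrix (columns: age, sex_<age>...).
#' @export
study_contrasts <- function(design) {
  groups <- levels(design$group)
  ages <- levels(design$age)
  ref <- ages[1]
  later <- ages[-1]
  C <- matrix(0, length(groups), 1 + length(ages),
              dimnames = list(groups, c("age", paste0("sex_", ages))))
  grp_age <- sub("\\.[MF]$", "", groups)
  grp_sex <- sub("^.*\\.", "", groups)
  C[grp_age %in% later, "age"] <- 1 / sum(grp_age %in% later)
  C[grp_age == ref, "age"] <- -1 / sum(grp_age == ref)
  for (a in ages) {
    C[grp_age == a & grp_sex == "M", paste0("sex_", a)] <- 1
    C[grp_age == a & grp_sex == "F", paste0("sex_", a)] <- -1
  }
  C
}

#' Stagewise differential expression testing
#'
#' Fits a negative-binomial GLM per gene on the 8-level age x sex group
#' factor (empirical-Bayes dispersion shrinkage toward a fitted trend),
#' screens genes with a joint likelihood-ratio omnibus test over the five
#' study contrasts (BH FDR across genes), and, for screened genes only,
#' confirms individual contrasts with Holm-adjusted p-values within each
#' gene (family-wise error control per post-hoc family).
#'
#' @param dge Filtered, TMM-normalized \code{DGEList}.
#' @param design A \code{sample_design} matching the columns of \code{dge}.
#' @param screen_fdr Omnibus BH-FDR threshold admitting genes to stage 2
#'   (default 0.05).
#' @return A list of class \code{de_result}: \code{table} (one row per gene:
#'   logFC per contrast, omnibus_p, omnibus_fdr, stage-2 Holm-adjusted p per
#'   contrast — NA for unscreened genes), \code{contrasts}, \code{dispersion},
#'   \code{screen_fdr}.
#' @export
fit_stagewise_de <- function(dge, design, screen_fdr = 0.05) {
  stopifnot(ncol(dge) == nrow(design))
  mm <- stats::model.matrix(~0 + group, data = design)
  colnames(mm) <- levels(design$group)
  dge <- edgeR::estimateDisp(dge, mm)
  fit <- edgeR::glmFit(dge, mm)
  C <- study_contrasts(design)
  omni <- edgeR::glmLRT(fit, contrast = C)
  omnibus_p <- omni$table$PValue
  omnibus_fdr <- stats::p.adjust(omnibus_p, method = "BH")

  lfc <- matrix(NA_real_, nrow(dge), ncol(C),
                dimnames = list(rownames(dge), colnames(C)))
  p_each <- lfc
  for (k in seq_len(ncol(C))) {
    lrt <- edgeR::glmLRT(fit, contrast = C[, k])
    lfc[, k] <- lrt$table$logFC
    p_each[, k] <- lrt$table$PValue
  }
  screened <- omnibus_fdr < screen_fdr
  stage2 <- matrix(NA_real_, nrow(dge), ncol(C),
                   dimnames = list(rownames(dge), paste0("holm_", colnames(C))))
  if (any(screened))
    stage2[screened, ] <- t(apply(p_each[screened, , drop = FALSE], 1,
                                  stats::p.adjust, method = "holm"))
  tab <- data.frame(gene_id = rownames(dge),
                    lfc, omnibus_p = omnibus_p, omnibus_fdr = omnibus_fdr,
                    stage2, dispersion = dge$tagwise.dispersion,
                    row.names = rownames(dge), check.names = FALSE)
  colnames(tab)[1 + seq_len(ncol(C))] <- paste0("logFC_", colnames(C))
  structure(list(table = tab, contrasts = C, screen_fdr = screen_fdr),
            class = "de_result")
}

#' Genes significant for a given contrast
#'
#' Stagewise significance: omnibus FDR below the screening threshold AND the
#' contrast's within-gene Holm-adjusted p below \code{alpha}.
#'
#' @param de A \code{de_result}.
#' @param contrast Contrast name ("age", "sex_d1", ...), or "any".
#' @param alpha Stage-2 significance level (default 0.05).
#' @return Character vector of gene ids.
#' @export
significant_genes <- function(de, contrast = "age", alpha = 0.05) {
  tab <- de$table
  cols <- if (identical(contrast, "any"))
    grep("^holm_", names(tab), value = TRUE)
  else paste0("holm_", contrast)
  stopifnot(all(cols %in% names(tab)))
  hit <- rowSums(tab[, cols, drop = FALSE] < alpha, na.rm = TRUE) > 0
  tab$gene_id[tab$omnibus_fdr < de$screen_fdr & hit]
}

#' The 27-letter developmental pattern alphabet
#'
#' Trajectory codes are 3-character strings over {L, E, H} giving the state
#' at 20 dph, 65 dph and adult relative to 1 dph. Twelve biologically
#' interpretable codes (change at exactly one time point, at the two middle
#' points, from 20 dph onwards, or from 65 dph onwards) form the selected
#' subset.
#'
#' @return list with \code{codes} (all 27) and \code{selected} (the 12).
#' @export
pattern_alphabet <- function() {
  g <- expand.grid(t3 = c("L", "E", "H"), t2 = c("L", "E", "H"),
                   t1 = c("L", "E", "H"), stringsAsFactors = FALSE)
  codes <- paste0(g$t1, g$t2, g$t3)
  selected <- c("LEE", "ELE", "EEL", "HEE", "EHE", "EEH",
                "LLE", "HHE", "LLL", "HHH", "ELL", "EHH")
  list(codes = sort(codes), selected = selected)
}

#' Classify developmental expression patterns
#'
#' For each gene, each later age is called H (higher) or L (lower) when its
#' mean log-cpm (sexes pooled) differs from the 1 dph mean by more than
#' \code{threshold_sd} pooled within-group standard deviations, else E;
#' under normality about 5% of null genes exceed the default 1.65 SD in a
#' given direction.
#'
#' @param logcpm Genes x samples log-cpm matrix.
#' @param design A \code{sample_design}.
#' @param threshold_sd SD multiple defining H/L calls (default 1.65).
#' @param sd_method "pooled" (within-group SD pooled over the 8 age x sex
#'   groups; default) or "per_age" (SD pooled over the reference and target
#'   age only).
#' @return data.frame: gene_id, code, selected, constant (zero-SD genes,
#'   forced to EEE).
#' @export
classify_patterns <- function(logcpm, design, threshold_sd = 1.65,
                              sd_method = c("pooled", "per_age")) {
  sd_method <- match.arg(sd_method)
  stopifnot(threshold_sd > 0, ncol(logcpm) == nrow(design))
  ages <- levels(design$age)
  if (min(table(design$group)) < 2)
    stop("need >= 2 replicates per group for SD estimation")
  grp <- design$group
  # per-gene within-group sums of squares and pooled SD
  gm <- t(apply(logcpm, 1, function(x) tapply(x, grp, mean)))
  center <- gm[, as.character(grp), drop = FALSE]
  ss_w <- rowSums((logcpm - center)^2)
  df_w <- ncol(logcpm) - nlevels(grp)
  s_pooled <- sqrt(ss_w / df_w)

  age_mean <- vapply(ages, function(a)
    rowMeans(logcpm[, design$age == a, drop = FALSE]), numeric(nrow(logcpm)))
  if (!is.matrix(age_mean))
    age_mean <- matrix(age_mean, 1, dimnames = list(rownames(logcpm), ages))
  ref <- ages[1]
  lab <- matrix("E", nrow(logcpm), length(ages) - 1,
                dimnames = list(rownames(logcpm), ages[-1]))
  for (a in ages[-1]) {
    s <- if (sd_method == "pooled") s_pooled else {
      sel <- design$age %in% c(ref, a)
      g2 <- droplevels(design$group[sel])
      x2 <- logcpm[, sel, drop = FALSE]
      gm2 <- t(apply(x2, 1, function(v) tapply(v, g2, mean)))
      sqrt(rowSums((x2 - gm2[, as.character(g2), drop = FALSE])^2) /
             (sum(sel) - nlevels(g2)))
    }
    d <- age_mean[, a] - age_mean[, ref]
    lab[d > threshold_sd * s & s > 0, a] <- "H"
    lab[d < -threshold_sd * s & s > 0, a] <- "L"
  }
  code <- apply(lab, 1, paste, collapse = "")
  constant <- s_pooled == 0
  code[constant] <- strrep("E", length(ages) - 1)
  data.frame(gene_id = rownames(logcpm), code = code,
             selected = code %in% pattern_alphabet()$selected,
             constant = constant, row.names = rownames(logcpm))
}
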