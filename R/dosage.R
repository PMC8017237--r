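#' Male:female expression ratios per age
#'
#' Per gene and age, the ratio of mean male cpm to mean female cpm
#' (cpm uses TMM-effective library sizes; the female mean gets a small
#' epsilon guard against division by zero). Unplaced "_random" fragments
#' are merged into their parent chromosome class. A ratio of 1 indicates
#' complete dosage compensation, 2 none.
#'
#' @param dge TMM-normalized \code{DGEList}.
#' @param design A \code{sample_design}; both sexes must be present at
#'   every age.
#' @param genes Annotation data.frame with gene_id and chrom_class.
#' @param epsilon Zero-denominator guard (default 1e-6).
#' @return data.frame: gene_id, chrom_class (merged: autosome, Z, W),
#'   ratio_<age> columns, zero_both_<age> logicals (no expression in either
#'   sex at that age: unclassifiable there).
#' @export
mf_ratios <- function(dge, design, genes, epsilon = 1e-6) {
  tab <- table(design$age, design$sex)
  if (any(tab == 0)) stop("an age is missing one sex")
  cpm <- edgeR::cpm(dge)
  ages <- levels(design$age)
  merged <- sub("^random_", "", genes$chrom_class)
  out <- data.frame(gene_id = rownames(cpm),
                    chrom_class = merged[match(rownames(cpm), genes$gene_id)],
                    row.names = rownames(cpm))
  for (a in ages) {
    m <- rowMeans(cpm[, design$age == a & design$sex == "M", drop = FALSE])
    f <- rowMeans(cpm[, design$age == a & design$sex == "F", drop = FALSE])
    out[[paste0("ratio_", a)]] <- m / (f + epsilon)
    out[[paste0("zero_both_", a)]] <- m == 0 & f == 0
  }
  out
}

#' Classify Z-linked genes by dosage-compensation history
#'
#' The cutoff is the \code{quantile} (default 95%) linear-interpolation
#' quantile of the autosomal M:F ratio distribution — computed per age by
#' default, or pooled over first and last age. Z genes are then classified
#' from the first and last age: below the cutoff at both = compensated
#' "from_birth"; at or above at first but below at last = "acquired";
#' at or above at both = "never". Genes compensated at birth but not in
#' adulthood fall outside the three-class scheme and are labeled "other";
#' genes with no expression in either sex at a boundary age are
#' unclassifiable ("NA").
#'
#' @param ratios Output of \code{mf_ratios}.
#' @param quantile Autosomal quantile defining the cutoff (default 0.95).
#' @param cutoff_mode "per_age" (default) or "pooled".
#' @return list of class \code{dosage_classification}: \code{table}
#'   (gene_id, ratio at first/last age, class), \code{cutoff} (named by
#'   age), \code{counts} (per class).
#' @export
classify_dosage <- function(ratios, quantile = 0.95,
                            cutoff_mode = c("per_age", "pooled")) {
  stopifnot(quantile > 0, quantile < 1)
  cutoff_mode <- match.arg(cutoff_mode)
  age_cols <- grep("^ratio_", names(ratios), value = TRUE)
  first <- age_cols[1]
  last <- age_cols[length(age_cols)]
  auto <- ratios$chrom_class == "autosome"
  if (sum(auto) < 20) stop("need >= 20 autosomal genes for a stable cutoff")
  zsel <- ratios$chrom_class == "Z"
  if (!any(zsel)) stop("no Z-linked genes to classify")
  if (cutoff_mode == "pooled") {
    cut_val <- stats::quantile(c(ratios[auto, first], ratios[auto, last]),
                               quantile, names = FALSE, type = 7)
    cutoff <- stats::setNames(rep(cut_val, 2), c(first, last))
  } else {
    cutoff <- vapply(c(first, last), function(cl)
      stats::quantile(ratios[auto, cl], quantile, names = FALSE, type = 7),
      numeric(1))
  }
  z <- ratios[zsel, , drop = FALSE]
  r1 <- z[[first]]
  r2 <- z[[last]]
  lo1 <- r1 < cutoff[[first]]
  lo2 <- r2 < cutoff[[last]]
  cls <- ifelse(lo1 & lo2, "from_birth",
                ifelse(!lo1 & lo2, "acquired",
                       ifelse(!lo1 & !lo2, "never", "other")))
  unclass_first <- z[[sub("^ratio_", "zero_both_", first)]]
  unclass_last <- z[[sub("^ratio_", "zero_both_", last)]]
  cls[unclass_first | unclass_last] <- NA_character_
  tab <- data.frame(gene_id = z$gene_id, ratio_first = r1, ratio_last = r2,
                    class = cls, row.names = z$gene_id)
  structure(list(table = tab, cutoff = cutoff,
                 counts = table(factor(cls, levels = c("from_birth", "acquired",
                                                       "never", "other"))),
                 quantile = quantile, cutoff_mode = cutoff_mode),
            class = "dosage_classification")
}

#' @export
print.dosage_classification <- function(x, ...) {
  cat(sprintf("dosage classes (cutoff %s at q=%.2f): %s\n",
              paste(sprintf("%.3f", x$cutoff), collapse = "/"), x$quantile,
              paste(names(x$counts), x$counts, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Binned M:F ratio distribution with loess smoothing
#'
#' Divides the observed ratio range into equal-width bins (default 1,000),
#' computes the percentage of genes per bin for each chromosome class, and
#' overlays a loess smooth of the percentage curve.
#'
#' @param ratios Numeric vector of M:F ratios for one age.
#' @param class Character vector of chromosome classes aligned to
#'   \code{ratios}.
#' @param n_bins Number of bins (default 1000).
#' @param span loess span (default 0.1; small, to track the narrow
#'   distribution peaks at this bin resolution).
#' @return data.frame: class, bin_mid, pct, smooth.
#' @export
ratio_distribution <- function(ratios, class, n_bins = 1000L, span = 0.1) {
  stopifnot(length(ratios) == length(class))
  ok <- is.finite(ratios)
  ratios <- ratios[ok]
  class <- class[ok]
  rng <- range(ratios)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- lapply(unique(class), function(cl) {
    h <- graphics::hist(ratios[class == cl], breaks = breaks, plot = FALSE)
    pct <- 100 * h$counts / sum(h$counts)
    sm <- stats::predict(stats::loess(pct ~ mids, span = span,
                                      degree = 1, family = "gaussian"))
    data.frame(class = cl, bin_mid = mids, pct = pct, smooth = sm)
  })
  do.call(rbind, out)
}

#' Mean expression across dosage classes: ANOVA with Tukey post hoc
#'
#' Each gene's log-cpm averaged over all samples is attributed to its
#' dosage class; differences in class means are tested by one-way ANOVA
#' with Tukey's HSD pairwise comparisons.
#'
#' @param logcpm Genes x samples log-cpm matrix.
#' @param classification A \code{dosage_classification}.
#' @return list: F, p, tukey (pairwise table: diff, lwr, upr, p_adj),
#'   n_per_class.
#' @export
dosage_group_stats <- function(logcpm, classification) {
  tab <- classification$table
  tab <- tab[!is.na(tab$class) & tab$class %in% c("from_birth", "acquired", "never") &
               tab$gene_id %in% rownames(logcpm), ]
  n_per <- table(tab$class)
  if (any(n_per < 2)) stop("a dosage class has fewer than 2 genes")
  d <- data.frame(mean_logcpm = rowMeans(logcpm[tab$gene_id, , drop = FALSE]),
                  class = factor(tab$class))
  fit <- stats::aov(mean_logcpm ~ class, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$class
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk), tk, row.names = NULL),
       n_per_class = n_per)
}

#' Pairwise chi-squared tests of a fraction across ages
#'
#' Given per-age counts of "hits" (e.g. Z-linked genes, or male-overexpressed
#' genes) among per-age totals (e.g. sex-DE genes), tests every pair of ages
#' with a 2x2 Pearson chi-squared and Bonferroni-corrects over the pairs
#' (4 ages = 6 tests).
#'
#' @param hits Named integer vector (by age) of hit counts.
#' @param totals Named integer vector (by age) of totals.
#' @return data.frame: age1, age2, chi2, p, p_bonf.
#' @export
pairwise_fraction_tests <- function(hits, totals) {
  stopifnot(identical(names(hits), names(totals)), all(hits <= totals))
  ages <- names(hits)
  prs <- utils::combn(ages, 2)
  rows <- apply(prs, 2, function(pr) {
    tab <- rbind(c(hits[pr[1]], totals[pr[1]] - hits[pr[1]]),
                 c(hits[pr[2]], totals[pr[2]] - hits[pr[2]]))
    tst <- chi2_2x2(tab)
    data.frame(age1 = pr[1], age2 = pr[2], chi2 = tst$chi2, p = tst$p)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(out$p * nrow(out), 1)
  out
}
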