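#' Simulation configuration
#'
#' Parameters of the synthetic dataset generator. Defaults emulate the
#' study conditions the analyses assume: a 4-age x 2-sex x 3-pool design,
#' negative-binomial counts with age/sex group structure, binomial
#' methylation counts with age trends and a hydroxymethylation fraction,
#' autosome/Z chromosome assignment with configurable dosage-compensation
#' classes, and promoter sequences with planted motifs. One global seed
#' fully determines the output; each stage derives a fixed child seed
#' (seed + 1: annotation, + 2: expression, + 3: methylation, + 4:
#' promoters) so stages can be regenerated independently.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_cpg_per_gene Promoter CpG/CpH sites per gene (default 5).
#' @param genic_cpg_per_gene Gene-body sites per gene (default 3).
#' @param n_intergenic Intergenic sites overall (default 200).
#' @param seed Global seed.
#' @param nb_dispersion Negative-binomial dispersion (default 0.05).
#' @param baseline_logcpm_range Range of baseline log2-cpm (default 1..8).
#' @param pattern_assignments Named character vector gene -> 3-letter
#'   pattern code, or NULL to assign \code{pattern_fraction} of genes
#'   randomly among the 12 selected codes.
#' @param pattern_fraction Fraction of genes given a non-null pattern when
#'   \code{pattern_assignments} is NULL (default 0.3).
#' @param effect_size_sd_units Pattern effect size in units of the
#'   within-group SD of log2 counts (default 3).
#' @param dosage_class_fractions Simplex over from_birth, acquired, never,
#'   autosomal_null; the first three are Z-linked.
#' @param meth_age_slope Logit-scale methylation shift per age step for
#'   dm-flagged sites (default 0.5).
#' @param dm_fraction Fraction of sites carrying the age trend (default 0.2).
#' @param cph_fraction Fraction of sites in CpH context (default 0.3).
#' @param hmc_fraction Hydroxymethylated fraction of the methylation signal,
#'   in [0, 1) (default 0.1).
#' @param coverage_mean Mean Poisson coverage per site and sample
#'   (default 20).
#' @param lib_size Expected library size per sample (default 5e6).
#' @param tf_fraction Fraction of genes flagged as transcription factors
#'   (default 0.1).
#' @param promoter_length Promoter sequence length, nt (default 2500,
#'   matching the -2000/+500 window).
#' @param bg_freqs Background nucleotide probabilities for promoter
#'   sequence simulation.
#' @param planted_motif A \code{pwm} whose consensus is planted in
#'   motif-positive promoters, or NULL.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000L, n_cpg_per_gene = 5L,
                       genic_cpg_per_gene = 3L, n_intergenic = 200L,
                       seed = 1L, nb_dispersion = 0.05,
                       baseline_logcpm_range = c(1, 8),
                       pattern_assignments = NULL, pattern_fraction = 0.3,
                       effect_size_sd_units = 3,
                       dosage_class_fractions = c(from_birth = 0.01,
                                                  acquired = 0.05,
                                                  never = 0.02,
                                                  autosomal_null = 0.92),
                       meth_age_slope = 0.5, dm_fraction = 0.2,
                       cph_fraction = 0.3, hmc_fraction = 0.1,
                       coverage_mean = 20, lib_size = 5e6,
                       tf_fraction = 0.1, promoter_length = 2500L,
                       bg_freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       planted_motif = NULL) {
  stopifnot(n_genes >= 1, nb_dispersion > 0, hmc_fraction >= 0,
            hmc_fraction < 1, coverage_mean > 0,
            abs(sum(dosage_class_fractions) - 1) < 1e-8,
            all(names(dosage_class_fractions) ==
                  c("from_birth", "acquired", "never", "autosomal_null")))
  if (!is.null(pattern_assignments)) {
    bad <- setdiff(unique(pattern_assignments), pattern_alphabet()$codes)
    if (length(bad))
      stop("pattern code(s) not in the 27-pattern alphabet: ",
           paste(bad, collapse = ", "))
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate gene annotation
#'
#' Genes are laid out head-to-tail with generous spacing on a handful of
#' autosomes, a Z chromosome (dosage classes per the configured fractions)
#' and matching "_random" fragments; strand alternates so both TSS
#' conventions are exercised.
#'
#' @param config A \code{sim_config}.
#' @return Annotation data.frame (as \code{read_annotation}) plus columns
#'   \code{dosage_class}.
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_genes
  cls <- sample(names(config$dosage_class_fractions), n, replace = TRUE,
                prob = config$dosage_class_fractions)
  chrom <- character(n)
  z <- cls != "autosomal_null"
  chrom[z] <- sample(c("Z", "Z_random"), sum(z), replace = TRUE, prob = c(0.9, 0.1))
  chrom[!z] <- sample(c(as.character(1:5), "2_random"), sum(!z),
                      replace = TRUE, prob = c(rep(0.19, 5), 0.05))
  width <- sample(2000:10000, n, replace = TRUE)
  ann <- data.frame(gene_id = sprintf("G%05d", seq_len(n)), chrom = chrom,
                    width = width, stringsAsFactors = FALSE)
  ann <- ann[order(ann$chrom), ]
  spacing <- 12000L
  start <- integer(n)
  for (ch in unique(ann$chrom)) {
    i <- which(ann$chrom == ch)
    start[i] <- 5000L + cumsum(c(0L, utils::head(ann$width[i], -1) + spacing))
  }
  ann$start <- start
  ann$end <- ann$start + ann$width - 1L
  ann$strand <- rep_len(c("+", "-"), n)
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  ann$chrom_class <- chrom_class(ann$chrom)
  ann$is_tf <- seq_len(n) %in% sample.int(n, round(config$tf_fraction * n))
  ann$dosage_class <- cls[match(ann$gene_id, sprintf("G%05d", seq_len(n)))]
  ann$width <- NULL
  ann <- ann[order(ann$gene_id), ]
  rownames(ann) <- ann$gene_id
  ann
}

#' @keywords internal
acquired_ratio <- function(age_idx, n_ages) {
  # log-linear interpolation of the M:F ratio from 2 at the first age to 1
  # at the last
  2^(1 - (age_idx - 1) / (n_ages - 1))
}

#' Simulate an expression count matrix with known truth
#'
#' Counts are negative-binomial with gene-specific means per age x sex
#' group. Pattern-assigned genes have the flagged later-age means shifted
#' by \code{effect_size_sd_units} within-group SDs of log2 counts; Z-linked
#' genes carry a male:female mean ratio trajectory per their dosage class
#' (2 throughout for "never", log-linear 2 -> 1 for "acquired", 1 for
#' "from_birth").
#'
#' @param config A \code{sim_config}.
#' @param design A \code{sample_design}.
#' @param genes Annotation from \code{simulate_annotation} (regenerated
#'   from the config when NULL).
#' @return list: \code{counts} (genes x samples integer matrix),
#'   \code{truth} (gene_id, pattern, dosage_class, mf_log2ratio per age,
#'   baseline_logcpm, sd_log2), \code{mu} (true mean matrix), \code{lib}
#'   (simulated library sizes).
#' @export
simulate_expression <- function(config, design, genes = NULL) {
  if (is.null(genes)) genes <- simulate_annotation(config)
  set.seed(config$seed + 2L)
  n <- config$n_genes
  ages <- levels(design$age)
  n_ages <- length(ages)
  base_lcpm <- stats::runif(n, config$baseline_logcpm_range[1],
                            config$baseline_logcpm_range[2])
  lib <- round(config$lib_size * stats::runif(nrow(design), 0.85, 1.15))
  base_mu <- 2^base_lcpm / 1e6 * mean(lib)
  # SD of log2 counts under NB(mu, phi): var(log X) ~ (1/mu + phi) (delta method)
  sd_log2 <- sqrt(1 / base_mu + config$nb_dispersion) / log(2)

  pat <- config$pattern_assignments
  if (is.null(pat)) {
    idx <- sample.int(n, round(config$pattern_fraction * n))
    pat <- stats::setNames(rep("EEE", n), genes$gene_id)
    pat[idx] <- sample(pattern_alphabet()$selected, length(idx), replace = TRUE)
  } else {
    full <- stats::setNames(rep("EEE", n), genes$gene_id)
    full[names(pat)] <- pat
    pat <- full
  }

  # per-gene, per-age log2 offsets from the pattern code (vs first age)
  age_off <- matrix(0, n, n_ages, dimnames = list(genes$gene_id, ages))
  for (t in 2:n_ages) {
    lv <- substr(pat, t - 1, t - 1)
    age_off[, t] <- ifelse(lv == "H", 1, ifelse(lv == "L", -1, 0)) *
      config$effect_size_sd_units * sd_log2
  }

  # per-gene, per-age male:female log2 ratio from the dosage class
  mf_l2r <- matrix(0, n, n_ages, dimnames = list(genes$gene_id, ages))
  dcls <- genes$dosage_class
  mf_l2r[dcls == "never", ] <- 1
  for (t in seq_len(n_ages))
    mf_l2r[dcls == "acquired", t] <- log2(acquired_ratio(t, n_ages))

  mu <- matrix(0, n, nrow(design),
               dimnames = list(genes$gene_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    t <- match(design$age[j], ages)
    sexadd <- if (design$sex[j] == "M") mf_l2r[, t] / 2 else -mf_l2r[, t] / 2
    mu[, j] <- 2^(log2(base_mu) + age_off[, t] + sexadd) * lib[j] / mean(lib)
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = n, dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"
  truth <- data.frame(gene_id = genes$gene_id, pattern = unname(pat),
                      dosage_class = dcls, baseline_logcpm = base_lcpm,
                      sd_log2 = sd_log2, row.names = genes$gene_id)
  truth <- cbind(truth, stats::setNames(as.data.frame(mf_l2r),
                                        paste0("mf_log2ratio_", ages)))
  list(counts = counts, truth = truth, mu = mu,
       lib = stats::setNames(lib, design$sample_id))
}

#' Simulate RRBS and oxRRBS methylation counts with known truth
#'
#' Sites are placed in promoters, gene bodies and intergenic space. Total
#' read counts are Poisson; methylated counts are binomial with a
#' logit-scale age trend at dm-flagged sites. The RRBS assay reads total
#' methylation (5mC + 5hmC); the oxRRBS assay reads beta * (1 -
#' hmc_fraction). CpH sites have a lower baseline than CpG sites.
#'
#' @param config A \code{sim_config}.
#' @param design A \code{sample_design}.
#' @param genes Annotation from \code{simulate_annotation} (regenerated
#'   when NULL).
#' @return list: \code{rrbs}, \code{oxrrbs} (\code{meth_mat}), \code{truth}
#'   (per site: dm_flag, baseline_logit, slope, true_hmc, region, gene_id,
#'   true beta per age).
#' @export
simulate_methylation <- function(config, design, genes = NULL) {
  if (is.null(genes)) genes <- simulate_annotation(config)
  set.seed(config$seed + 3L)
  ages <- levels(design$age)
  n_ages <- length(ages)

  place <- function(gene, region) {
    k <- if (region == "promoter") config$n_cpg_per_gene else config$genic_cpg_per_gene
    if (k == 0) return(NULL)
    if (region == "promoter") {
      lo <- if (gene$strand == "+") gene$tss - 2000L else gene$tss - 500L
      hi <- if (gene$strand == "+") gene$tss + 500L else gene$tss + 2000L
    } else {
      lo <- gene$start
      hi <- gene$end
    }
    pos <- sort(sample(max(lo, 1L):hi, k))
    data.frame(chrom = gene$chrom, pos = pos, region = region,
               gene_id = gene$gene_id, stringsAsFactors = FALSE)
  }
  per_gene <- lapply(seq_len(nrow(genes)), function(i)
    rbind(place(genes[i, ], "promoter"), place(genes[i, ], "genic")))
  sites <- do.call(rbind, per_gene)
  if (config$n_intergenic > 0) {
    inter <- data.frame(chrom = "9", pos = sort(sample.int(1e6, config$n_intergenic)),
                        region = "intergenic", gene_id = NA_character_,
                        stringsAsFactors = FALSE)
    sites <- rbind(sites, inter)
  }
  ns <- nrow(sites)
  sites$strand <- sample(c("+", "-"), ns, replace = TRUE)
  sites$context <- ifelse(stats::runif(ns) < config$cph_fraction, "CpH", "CpG")
  dup <- duplicated(paste(sites$chrom, sites$pos, sites$strand, sites$context))
  sites <- sites[!dup, ]
  ns <- nrow(sites)

  base_logit <- ifelse(sites$context == "CpG",
                       stats::rnorm(ns, stats::qlogis(0.20), 0.5),
                       stats::rnorm(ns, stats::qlogis(0.05), 0.5))
  dm <- stats::runif(ns) < config$dm_fraction & config$meth_age_slope != 0
  slope <- ifelse(dm, config$meth_age_slope, 0)

  beta_age <- sapply(seq_len(n_ages), function(t)
    stats::plogis(base_logit + slope * (t - 1)))
  colnames(beta_age) <- ages

  site_df <- sites[, c("chrom", "pos", "strand", "context")]
  draw_assay <- function(scale_beta) {
    total <- matrix(stats::rpois(ns * nrow(design), config$coverage_mean),
                    ns, nrow(design),
                    dimnames = list(NULL, design$sample_id))
    p <- beta_age[, match(as.character(design$age), ages), drop = FALSE] * scale_beta
    meth <- matrix(stats::rbinom(length(total), as.vector(total), as.vector(p)),
                   ns, nrow(design), dimnames = dimnames(total))
    list(meth = meth, total = total)
  }
  r <- draw_assay(1)
  o <- draw_assay(1 - config$hmc_fraction)
  rrbs <- meth_matrix(site_df, r$meth, r$total, "rrbs")
  oxrrbs <- meth_matrix(site_df, o$meth, o$total, "oxrrbs")
  truth <- data.frame(site = site_key(site_df), region = sites$region,
                      gene_id = sites$gene_id, context = sites$context,
                      dm_flag = dm, baseline_logit = base_logit,
                      slope = slope,
                      true_hmc = config$hmc_fraction *
                        rowMeans(beta_age),
                      row.names = site_key(site_df))
  truth <- cbind(truth, stats::setNames(as.data.frame(beta_age),
                                        paste0("beta_", ages)))
  list(rrbs = rrbs, oxrrbs = oxrrbs, truth = truth)
}

#' Simulate coupled methylation and expression with a known slope
#'
#' Generates per-gene promoter (or genic) cytosine M-values with gene,
#' sample and site-level variation, and log-cpm values that depend
#' linearly on the gene-sample mean M-value with the given slope, plus
#' gene and sample random intercepts — the generative model matched by
#' \code{methylation_expression_mixed_model}, for parameter-recovery
#' checks.
#'
#' @param n_genes Number of genes (default 500).
#' @param design A \code{sample_design}.
#' @param slope True slope, log2-cpm per M-value unit (default -0.04).
#' @param n_sites_per_gene Cytosines per gene (default 5).
#' @param seed Seed.
#' @param sd_gene_M,sd_sample_M,sd_M SDs of the gene-level, sample-level
#'   and residual components of the latent mean M-value.
#' @param sd_site Site-level M noise around the gene-sample mean.
#' @param sd_gene_expr,sd_sample_expr,sd_expr SDs of gene intercepts,
#'   sample intercepts and residual expression noise.
#' @param region Annotation label for the generated sites.
#' @return list: \code{logcpm} (genes x samples), \code{M} (sites x
#'   samples), \code{site_annot} (annotation, gene_id, unique_gene),
#'   \code{slope}.
#' @export
simulate_coupled_methylation_expression <- function(
    n_genes = 500L, design = sample_design(), slope = -0.04,
    n_sites_per_gene = 5L, seed = 1L,
    sd_gene_M = 2, sd_sample_M = 0.3, sd_M = 1, sd_site = 0.5,
    sd_gene_expr = 1, sd_sample_expr = 0.2, sd_expr = 0.3,
    region = "promoter") {
  set.seed(seed)
  n_s <- nrow(design)
  gid <- sprintf("G%05d", seq_len(n_genes))
  latentM <- stats::rnorm(n_genes, 0, sd_gene_M) +
    matrix(stats::rnorm(n_genes * n_s, 0, sd_M), n_genes) +
    rep(stats::rnorm(n_s, 0, sd_sample_M), each = n_genes)
  dim(latentM) <- c(n_genes, n_s)
  dimnames(latentM) <- list(gid, design$sample_id)
  logcpm <- stats::rnorm(n_genes, 5, sd_gene_expr) + slope * latentM +
    rep(stats::rnorm(n_s, 0, sd_sample_expr), each = n_genes) +
    matrix(stats::rnorm(n_genes * n_s, 0, sd_expr), n_genes)
  dimnames(logcpm) <- dimnames(latentM)
  k <- n_sites_per_gene
  M <- latentM[rep(seq_len(n_genes), each = k), , drop = FALSE] +
    matrix(stats::rnorm(n_genes * k * n_s, 0, sd_site), n_genes * k)
  rownames(M) <- sprintf("%s_cpg%d", rep(gid, each = k), rep(seq_len(k), n_genes))
  site_annot <- data.frame(annotation = region,
                           gene_id = rep(gid, each = k),
                           unique_gene = TRUE, row.names = rownames(M))
  list(logcpm = logcpm, M = M, site_annot = site_annot, slope = slope)
}

#' Simulate promoter sequences with planted motif occurrences
#'
#' Background sequence is i.i.d. from the configured nucleotide
#' frequencies; for motif-positive genes one exact consensus occurrence of
#' the planted PWM is inserted at a random position.
#'
#' @param config A \code{sim_config} with \code{planted_motif} set (unless
#'   \code{positive_genes} is empty).
#' @param genes Annotation (regenerated when NULL).
#' @param positive_genes Gene ids receiving a planted occurrence; default:
#'   none.
#' @return list: \code{seqs} (named character vector, one promoter of
#'   \code{promoter_length} nt per gene), \code{truth} (named logical:
#'   motif planted).
#' @export
simulate_promoters <- function(config, genes = NULL, positive_genes = character()) {
  if (is.null(genes)) genes <- simulate_annotation(config)
  set.seed(config$seed + 4L)
  L <- config$promoter_length
  n <- nrow(genes)
  freqs <- config$bg_freqs[BASES]
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(BASES, L, replace = TRUE, prob = freqs), collapse = ""),
    character(1))
  names(seqs) <- genes$gene_id
  planted <- stats::setNames(genes$gene_id %in% positive_genes, genes$gene_id)
  if (any(planted)) {
    if (is.null(config$planted_motif))
      stop("positive_genes given but config$planted_motif is NULL")
    cons <- pwm_consensus(config$planted_motif)
    if (nchar(cons) > L) stop("motif longer than promoter")
    for (g in names(planted)[planted]) {
      at <- sample.int(L - nchar(cons) + 1L, 1L)
      substr(seqs[g], at, at + nchar(cons) - 1L) <- cons
    }
  }
  list(seqs = seqs, truth = planted)
}
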