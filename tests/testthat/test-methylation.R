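test_that("M-value transform: fixed points, symmetry, monotonicity", {
  one <- function(meth, total) {
    m <- list(meth = matrix(meth, 1), total = matrix(total, 1))
    v <- compute_m_values(m)
    c(beta = v$beta[1], M = v$M[1])
  }
  expect_equal(unname(one(5, 10)), c(0.5, 0))
  # beta = 0: M = log2(0.01 / 1.01)
  expect_equal(unname(one(0, 10)["M"]), log2(0.01 / 1.01))
  expect_equal(unname(one(0, 10)["M"]), -6.658, tolerance = 1e-3)
  # antisymmetry about beta = 0.5
  expect_equal(unname(one(10, 10)["M"]), -unname(one(0, 10)["M"]))
  # strictly increasing in beta
  Ms <- vapply(0:20, function(k) unname(one(k, 20)["M"]), numeric(1))
  expect_true(all(diff(Ms) > 0))
  # total = 0 yields NA, never 0/0
  expect_true(is.na(one(0, 0)["beta"]))
})

test_that("site filters apply exact coverage and methylated-read boundaries", {
  d <- full_design
  mk <- function(total_per_sample, meth_total) {
    total <- matrix(total_per_sample, 1, 24, dimnames = list(NULL, d$sample_id))
    meth <- matrix(0L, 1, 24, dimnames = dimnames(total))
    meth[1, seq_len(meth_total)] <- 1L
    meth_matrix(data.frame(chrom = "1", pos = 1L, strand = "+", context = "CpG"),
                meth, total, "rrbs")
  }
  # mean coverage exactly 5 and 6 methylated reads: retained
  expect_equal(nrow(filter_cytosines(mk(5L, 6L))$sites), 1)
  # sum(total) = 119 -> mean 4.958: removed
  m2 <- mk(5L, 6L)
  m2$total[1, 1] <- 4L
  expect_equal(sum(m2$total), 119)
  expect_equal(nrow(filter_cytosines(m2)$sites), 0)
  # only 5 methylated reads despite high coverage: removed
  expect_equal(nrow(filter_cytosines(mk(50L, 5L))$sites), 0)
})

test_that("filters are invariant under sample permutation", {
  d <- full_design
  cfg <- sim_config(n_genes = 30, seed = 44, coverage_mean = 6)
  ms <- simulate_methylation(cfg, d)
  perm <- sample(24)
  mp <- ms$rrbs
  mp$meth <- mp$meth[, perm]
  mp$total <- mp$total[, perm]
  expect_identical(rownames(filter_cytosines(ms$rrbs)$sites),
                   rownames(filter_cytosines(mp)$sites))
})

test_that("moderated fit: prior limits, convexity, and limma agreement", {
  d <- full_design
  cfg <- sim_config(n_genes = 60, seed = 45)
  ms <- simulate_methylation(cfg, d)
  M <- compute_m_values(filter_cytosines(ms$rrbs))$M
  M <- M[rowSums(is.finite(M)) == 24, ]

  # prior df 0 recovers ordinary least-squares t
  dm0 <- fit_moderated_dm(M, d, prior_df = 0)
  mm <- model.matrix(~0 + group, data = d)
  colnames(mm) <- levels(d$group)
  cfit <- limma::contrasts.fit(limma::lmFit(M, mm), study_contrasts(d))
  t_ols <- cfit$coefficients / (cfit$stdev.unscaled * cfit$sigma)
  expect_equal(dm0$table$t_age, unname(t_ols[, "age"]), tolerance = 1e-10)

  # infinite prior pins every posterior variance at the prior value
  dmInf <- fit_moderated_dm(M, d, prior_df = Inf)
  expect_equal(var(dmInf$s2_post), 0)

  # estimated prior: posterior variance lies between the site MLE and the prior
  dm <- fit_moderated_dm(M, d)
  s02 <- (dm$s2_post[1] * (dm$df_prior + dm$df_residual[1]) -
            dm$df_residual[1] * dm$s2[1]) / dm$df_prior
  lo <- pmin(dm$s2, s02)
  hi <- pmax(dm$s2, s02)
  expect_true(all(dm$s2_post >= lo - 1e-12 & dm$s2_post <= hi + 1e-12))

  # full agreement with the reference moderated-statistics implementation
  eb <- limma::eBayes(cfit)
  expect_equal(dm$table$F, unname(eb$F), tolerance = 1e-10)
  expect_equal(dm$table$omnibus_p, unname(eb$F.p.value), tolerance = 1e-10)
  expect_equal(dm$table$t_age, unname(eb$t[, "age"]), tolerance = 1e-10)
})

test_that("subset FDR on the full set reproduces the original q-values", {
  d <- full_design
  cfg <- sim_config(n_genes = 50, seed = 46, meth_age_slope = 0.8)
  ms <- simulate_methylation(cfg, d)
  M <- compute_m_values(filter_cytosines(ms$rrbs))$M
  dm <- fit_moderated_dm(M, d, min_samples = 20)
  expect_equal(unname(subset_fdr(dm, seq_len(nrow(dm$table)))),
               dm$table$omnibus_fdr)
  # a strict subset generally changes the q-values
  sub <- seq_len(floor(nrow(dm$table) / 2))
  q_sub <- subset_fdr(dm, sub)
  expect_equal(length(q_sub), length(sub))
  expect_true(all(q_sub >= dm$table$omnibus_p[sub] - 1e-12))
})

test_that("hydroxymethylation subtraction: arithmetic, clipping, matching", {
  site <- data.frame(chrom = "1", pos = 10L, strand = "+", context = "CpG")
  mk <- function(meth, total, assay)
    meth_matrix(site, matrix(as.integer(meth), 1, dimnames = list(NULL, "s1")),
                matrix(as.integer(total), 1, dimnames = list(NULL, "s1")), assay)
  h <- subtract_hydroxymethylation(mk(5, 10, "rrbs"), mk(3, 10, "oxrrbs"))
  expect_equal(h$hmc[1, 1], 0.2)
  expect_false(h$clipped[1, 1])
  # oxRRBS above RRBS: clipped to 0 and flagged
  h2 <- subtract_hydroxymethylation(mk(2, 10, "rrbs"), mk(3, 10, "oxrrbs"))
  expect_equal(h2$hmc[1, 1], 0)
  expect_true(h2$clipped[1, 1])
  expect_equal(h2$raw[1, 1], -0.1)
  # disjoint site sets are an error
  other <- mk(3, 10, "oxrrbs")
  other$sites$pos <- 99L
  rownames(other$sites) <- NULL
  expect_error(subtract_hydroxymethylation(mk(5, 10, "rrbs"), other),
               "no overlapping sites")
})

test_that("hmc estimate is in range and unbiased at high coverage under the null", {
  d <- full_design
  cfg <- sim_config(n_genes = 50, seed = 47, hmc_fraction = 0, coverage_mean = 200)
  ms <- simulate_methylation(cfg, d)
  h <- subtract_hydroxymethylation(ms$rrbs, ms$oxrrbs)
  expect_true(all(h$hmc >= 0 & h$hmc <= 1, na.rm = TRUE))
  expect_lt(abs(mean(h$raw, na.rm = TRUE)), 0.003)
})

test_that("cytosine annotation: promoter window, priority, multi-gene sites", {
  genes <- data.frame(gene_id = c("A", "B"),
                      chrom = "1", start = c(10000L, 12300L),
                      end = c(12000L, 20000L), strand = c("+", "+"),
                      tss = c(10000L, 12300L),
                      chrom_class = "autosome", is_tf = FALSE)
  sites <- data.frame(chrom = "1",
                      pos = c(9900L,   # 100 bp upstream of A's TSS -> promoter
                              11500L,  # mid-gene A, but also in B's promoter
                              20000L,  # gene B body end -> genic
                              50000L,  # far away -> intergenic
                              10500L)) # inside A body and A promoter
  a <- annotate_cytosines(sites, genes)
  expect_equal(a$annotation, c("promoter", "promoter", "genic", "intergenic",
                               "promoter"))
  expect_equal(a$gene_ids[2], "A,B")
  expect_false(a$unique_gene[2])
  expect_true(a$unique_gene[3])
  expect_equal(a$gene_id[3], "B")
  # minus-strand promoter extends downstream of the TSS coordinate
  gm <- data.frame(gene_id = "C", chrom = "1", start = 1000L, end = 2000L,
                   strand = "-", tss = 2000L, chrom_class = "autosome",
                   is_tf = FALSE)
  am <- annotate_cytosines(data.frame(chrom = "1", pos = c(3500L, 4600L)), gm)
  expect_equal(am$annotation, c("promoter", "intergenic"))
})
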