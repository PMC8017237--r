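test_that("TMM factors: symmetry, scale invariance, geometric mean 1", {
  set.seed(1)
  counts <- matrix(rpois(400, 60), 200, 2, dimnames = list(NULL, c("s1", "s2")))
  # identical samples
  dge <- edgeR::DGEList(cbind(s1 = counts[, 1], s2 = counts[, 1]))
  f <- normalize_counts(dge)$samples$norm.factors
  expect_equal(f, c(1, 1))
  # global doubling is absorbed by the library size
  dge2 <- edgeR::DGEList(cbind(s1 = counts[, 1], s2 = 2L * counts[, 1]))
  expect_equal(normalize_counts(dge2)$samples$norm.factors, c(1, 1))
  # rescaling every count leaves factors unchanged; geometric mean is 1
  dge3 <- edgeR::DGEList(counts)
  dge4 <- edgeR::DGEList(counts * 3L)
  f3 <- normalize_counts(dge3)$samples$norm.factors
  f4 <- normalize_counts(dge4)$samples$norm.factors
  expect_equal(f3, f4)
  expect_equal(prod(f3)^(1 / length(f3)), 1, tolerance = 1e-12)
})

test_that("TMM factor equals the hand-computed trimmed weighted mean of M-values", {
  # 6 genes, 4 sharing one M-value, 2 extreme outliers trimmed symmetrically:
  # the doubly trimmed weighted mean is the common M regardless of weights
  lib1 <- 1000L
  c1 <- c(100L, 100L, 100L, 100L, 500L, 100L)
  # sample 2: common genes scaled by 2^0.5 relative to sample 1 after
  # library normalization; outliers at M = +4 and -4
  ratio <- 2^0.5
  c2 <- as.integer(round(c(100 * ratio, 100 * ratio, 100 * ratio, 100 * ratio,
                           500 * ratio * 2^4, 100 * ratio * 2^-4)))
  dge <- edgeR::DGEList(cbind(s1 = c1, s2 = c2))
  f <- normalize_counts(dge)$samples$norm.factors
  M_common <- log2((c2[1] / sum(c2)) / (c1[1] / sum(c1)))
  # factors have geometric mean 1, so f2/f1 = 2^{M_common}
  expect_equal(log2(f[2] / f[1]), M_common, tolerance = 1e-6)
})

test_that("low-expression filter applies the 22-of-24 rule at the boundary", {
  d <- full_design
  lib <- 1e6
  mk <- function(cpm_by_sample) as.integer(round(cpm_by_sample * lib / 1e6))
  counts <- rbind(
    removed = mk(c(rep(0.5, 23), 2.0)),     # cpm < 1 in 23 samples
    kept = mk(c(rep(0.5, 21), 2, 2, 2)),    # cpm < 1 in exactly 21
    high = mk(rep(50, 24)))
  # add a constant high gene so library sizes are ~1e6 per sample
  filler <- matrix(as.integer(lib - colSums(counts)), 1, 24)
  rownames(filler) <- "filler"
  dge <- edgeR::DGEList(rbind(counts, filler))
  colnames(dge) <- d$sample_id
  kept <- rownames(filter_low_expression(dge))
  expect_false("removed" %in% kept)
  expect_true(all(c("kept", "high") %in% kept))
  # a matrix where every gene is low-expressed empties out
  alllow <- edgeR::DGEList(rbind(low = mk(rep(0.2, 24)), filler))
  colnames(alllow) <- d$sample_id
  filt <- filter_low_expression(alllow[1, , keep.lib.sizes = TRUE])
  expect_equal(nrow(filt), 0)
  # and an already-empty matrix passes through
  expect_equal(nrow(filter_low_expression(filt)), 0)
})

test_that("the age contrast is the mean later-age effect versus 1 dph", {
  d <- full_design
  C <- study_contrasts(d)
  expect_equal(dim(C), c(8, 5))
  expect_equal(sum(C[, "age"]), 0)
  # group log-means d1: 1, later ages: 3 -> age logFC = 2
  mu <- setNames(ifelse(grepl("^d1\\.", levels(d$group)), 1, 3), levels(d$group))
  expect_equal(drop(mu %*% C)[["age"]], 2)
  # sex contrasts isolate M - F within one age
  mu_sex <- setNames(as.numeric(grepl("\\.M$", levels(d$group))), levels(d$group))
  expect_equal(unname(drop(mu_sex %*% C)[paste0("sex_", levels(d$age))]),
               rep(1, 4))
})

test_that("no gene has stage-2 results without passing the omnibus screen", {
  d <- full_design
  cfg <- sim_config(n_genes = 300, seed = 31)
  sim <- simulate_expression(cfg, d)
  dge <- normalize_counts(filter_low_expression(
    edgeR::DGEList(sim$counts, group = d$group)))
  de <- fit_stagewise_de(dge, d)
  tab <- de$table
  holm_cols <- grep("^holm_", names(tab))
  has_stage2 <- rowSums(!is.na(tab[, holm_cols])) > 0
  expect_true(all(tab$omnibus_fdr[has_stage2] < de$screen_fdr))
  expect_true(all(!has_stage2[tab$omnibus_fdr >= de$screen_fdr]))
  expect_true(all(tab$omnibus_p >= 0 & tab$omnibus_p <= 1))
  # Holm within gene never decreases a p-value
  expect_true(all(tab[has_stage2, holm_cols] >=
                    tab[has_stage2, grep("^holm_", names(tab))] - 1e-12))
})

test_that("pattern alphabet has 27 codes and the 12 selected ones", {
  pa <- pattern_alphabet()
  expect_length(pa$codes, 27)
  expect_length(pa$selected, 12)
  expect_true(all(c("HHH", "LLL") %in% pa$selected))
  expect_true("EEE" %in% pa$codes)
  expect_false("EEE" %in% pa$selected)
  expect_true(all(pa$selected %in% pa$codes))
  expect_false(anyDuplicated(pa$codes) > 0)
})

test_that("1.65 SD corresponds to about 5% one-sided exceedance under normality", {
  expect_lt(abs(pnorm(1.65, lower.tail = FALSE) - 0.05), 0.005)
})

test_that("pattern calls follow the threshold arithmetic", {
  d <- full_design
  build <- function(means_by_age, s) {
    # exact within-group SD s and exact group means
    base <- c(-1, 0, 1) * s  # sample SD of this triplet is exactly s
    x <- numeric(24)
    for (a in levels(d$age)) for (sx in levels(d$sex))
      x[d$age == a & d$sex == sx] <- means_by_age[[a]] + base
    matrix(x, 1, 24, dimnames = list("g", d$sample_id))
  }
  # means (d1 5, later 6), s = 0.4: +1 > 1.65*0.4 -> HHH
  m1 <- build(c(d1 = 5, d20 = 6, d65 = 6, adult = 6), 0.4)
  expect_equal(classify_patterns(m1, d)$code, "HHH")
  # d20 one unit below d1 -> LEE
  m2 <- build(c(d1 = 5, d20 = 4, d65 = 5, adult = 5), 0.4)
  p2 <- classify_patterns(m2, d)
  expect_equal(p2$code, "LEE")
  expect_true(p2$selected)
  # all equal -> EEE, not selected
  m3 <- build(c(d1 = 5, d20 = 5, d65 = 5, adult = 5), 0.4)
  p3 <- classify_patterns(m3, d)
  expect_equal(p3$code, "EEE")
  expect_false(p3$selected)
  # constant gene: zero SD flagged, forced to EEE
  m4 <- matrix(5, 1, 24, dimnames = list("g", d$sample_id))
  p4 <- classify_patterns(m4, d)
  expect_equal(p4$code, "EEE")
  expect_true(p4$constant)
  # a diff just below the threshold stays E: 0.65 < 1.65 * 0.4
  m5 <- build(c(d1 = 5, d20 = 5.65, d65 = 5, adult = 5), 0.4)
  expect_equal(classify_patterns(m5, d)$code, "EEE")
})

test_that("dispersion shrinkage approaches its limits", {
  d <- full_design
  cfg <- sim_config(n_genes = 150, seed = 41)
  sim <- simulate_expression(cfg, d)
  dge <- normalize_counts(edgeR::DGEList(sim$counts, group = d$group))
  mm <- model.matrix(~0 + group, data = d)
  heavy <- edgeR::estimateDisp(dge, mm, prior.df = 1e8)
  expect_equal(heavy$tagwise.dispersion, heavy$trended.dispersion,
               tolerance = 1e-3)
  light <- edgeR::estimateDisp(dge, mm, prior.df = 0)
  # with no prior weight tagwise estimates move off the trend
  expect_gt(sd(light$tagwise.dispersion - light$trended.dispersion), 0)
})
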