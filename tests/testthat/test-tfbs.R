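test_that("length-1 PWM scan matches full enumeration", {
  p1 <- make_pwm("A1", matrix(c(1, 0, 0, 0), 4, 1), pseudocount = 0)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  hits <- scan_sequences(c(s1 = "ACGT"), p1, tfbs_config(p_threshold = 0.3),
                         background = bg)
  fwd <- hits[hits$strand == "+", ]
  rev <- hits[hits$strand == "-", ]
  expect_equal(fwd$pos, 1)       # the single A
  expect_equal(fwd$p, 0.25)
  expect_equal(rev$pos, 4)       # T on the forward strand matches A on reverse
  expect_equal(rev$p, 0.25)
})

test_that("exact DP p-values equal brute-force enumeration for short motifs", {
  set.seed(7)
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  for (L in c(2, 4, 6, 8)) {
    counts <- matrix(rgamma(4 * L, 2), 4)
    pwm <- make_pwm(paste0("r", L), counts, pseudocount = 0.25)
    K <- pwm_score_matrix(pwm, bg)
    dist <- pwm_score_distribution(K, bg)
    # distribution integrates to 1 within discretization/fp error
    expect_lt(abs(sum(dist$prob) - 1), 1e-6)
    # tail probabilities agree with enumeration over all 4^L words at
    # several cutoffs spanning the score range
    for (q in c(0.5, 0.9, 0.99)) {
      cutoff <- dist$score[which(dist$tail < 1 - q)[1]]
      expect_equal(sum(dist$prob[dist$score >= cutoff]),
                   brute_force_tail(K, bg, cutoff), tolerance = 1e-12)
    }
  }
})

test_that("scanning is strand-symmetric", {
  set.seed(8)
  pwm <- make_pwm("asym", matrix(rgamma(20, 1), 4), pseudocount = 0.3)
  seqs <- setNames(vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""),
    character(1)), paste0("s", 1:10))
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  seqs_rc <- setNames(vapply(seqs, rc, character(1)), names(seqs))
  cfg <- tfbs_config(p_threshold = 5e-3)
  h1 <- scan_sequences(seqs, pwm, cfg)
  h2 <- scan_sequences(seqs_rc, pwm, cfg)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(as.vector(table(factor(h1$seq_id, names(seqs)))),
               as.vector(table(factor(h2$seq_id, names(seqs)))))
})

test_that("windows containing N are skipped; all-N yields nothing", {
  pwm <- planted_pwm()
  expect_equal(nrow(scan_sequences(c(x = strrep("N", 100)), pwm,
                                   tfbs_config(p_threshold = 0.5))), 0)
  # invalid characters are an error, motif longer than sequence is not
  expect_error(scan_sequences(c(x = "ACGU"), pwm), "invalid alphabet")
  expect_equal(nrow(scan_sequences(c(x = "ACG"), pwm)), 0)
})

test_that("enrichment chi-squared equals the closed form and handles edge tables", {
  # [[30,70],[10,90]] -> 12.5
  tab <- rbind(c(30, 70), c(10, 90))
  expect_equal(pearson_chi2(tab), 12.5)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(unname(ct$statistic), 12.5)
  # random tables: library statistic equals the closed form
  set.seed(9)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 40) + 1, 2)
    expect_equal(unname(suppressWarnings(chisq.test(t2, correct = FALSE))$statistic),
                 pearson_chi2(t2), tolerance = 1e-12)
  }
})

test_that("motif enrichment: direction, symmetry, and degenerate margins", {
  set.seed(10)
  pwm <- planted_pwm()
  cons <- pwm_consensus(pwm)
  rand_seq <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = ""),
    character(1))
  fg <- setNames(rand_seq(30), paste0("f", 1:30))
  bg <- setNames(rand_seq(30), paste0("b", 1:30))
  substr(fg[1:25], 50, 49 + nchar(cons)) <- cons
  res <- motif_enrichment(fg, bg, list(pwm))
  expect_gte(res$fg_hits, 25)
  expect_gt(res$chi2, 0)
  expect_gt(res$log2fc, 0)
  expect_true(res$q >= res$p)
  # swapping fg and bg leaves the statistic unchanged, flips the direction
  res2 <- motif_enrichment(bg, fg, list(pwm))
  expect_equal(res2$chi2, res$chi2)
  expect_equal(res2$log2fc, -res$log2fc, tolerance = 1e-12)
  # equal proportions: chi2 = 0, p = 1
  res3 <- motif_enrichment(fg, setNames(fg, paste0("c", seq_along(fg))),
                           list(pwm))
  expect_equal(res3$chi2, 0)
  expect_equal(res3$p, 1)
  # zero margin reported as missing with a reason
  none <- setNames(rep(strrep("T", 100), 10), paste0("n", 1:10))
  none2 <- setNames(rep(strrep("T", 100), 10), paste0("m", 1:10))
  pureA <- make_pwm("pA", matrix(c(40, 0, 0, 0), 4, 5), pseudocount = 0.01)
  res4 <- motif_enrichment(none, none2, list(pureA),
                           tfbs_config(p_threshold = 1e-3),
                           background = c(A = .25, C = .25, G = .25, T = .25))
  expect_true(is.na(res4$chi2))
  expect_match(res4$note, "zero margin")
})

test_that("CpG flank windows have the right span and truncation handling", {
  genome <- c(chr1 = paste(rep("ACGT", 500), collapse = ""))
  fl <- extract_flanks(data.frame(chrom = "chr1", pos = 1000L), genome, 50L)
  expect_equal(nchar(fl$seqs[[1]]), 100)
  expect_false(fl$truncated[1])
  # site near the chromosome start is truncated and flagged
  fl2 <- extract_flanks(data.frame(chrom = "chr1", pos = 10L), genome, 50L)
  expect_equal(nchar(fl2$seqs[[1]]), 59)  # positions 1..59
  expect_true(fl2$truncated[1])
  expect_error(extract_flanks(data.frame(chrom = "chrX", pos = 5L), genome),
               "unknown chromosome")
})

test_that("permuting DM labels removes flank enrichment", {
  set.seed(11)
  pwm <- planted_pwm()
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 60000, replace = TRUE),
                           collapse = ""))
  pos <- sort(sample(200:59800, 120))
  lab <- sample(c(TRUE, FALSE), 120, replace = TRUE)  # arbitrary permuted labels
  res <- cpg_flank_enrichment(data.frame(chrom = "chr1", pos = pos[lab]),
                              data.frame(chrom = "chr1", pos = pos[!lab]),
                              genome, list(pwm, make_pwm("d", matrix(1:12, 4))))
  expect_equal(sum(res$q < 0.05, na.rm = TRUE), 0)
})
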