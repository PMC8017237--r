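# Shared fixtures, all built in code at test time.

full_design <- sample_design()

# a tiny two-sample design for io round-trips
mini_design <- function() {
  d <- data.frame(sample_id = c("s1", "s2"),
                  age = factor(c("d1", "d1"), levels = c("d1", "d20", "d65", "adult"),
                               ordered = TRUE),
                  sex = factor(c("M", "F"), levels = c("M", "F")),
                  pool = c(1L, 1L), pool_size = 3L)
  d$group <- finchdev:::design_group(d)
  rownames(d) <- d$sample_id
  class(d) <- c("sample_design", "data.frame")
  d
}

# deterministic PWM with consensus ACGTACGT, strong but not degenerate
planted_pwm <- function() {
  make_pwm("planted", matrix(c(9, 0, 0, 0, 0, 9, 0, 0, 0, 0, 9, 0, 0, 0, 0, 9,
                               9, 0, 0, 0, 0, 9, 0, 0, 0, 0, 9, 0, 0, 0, 0, 9),
                             nrow = 4), pseudocount = 0.5)
}

# brute-force PWM match p-value over all 4^L words; independent of the DP
brute_force_tail <- function(K, background, cutoff) {
  L <- ncol(K)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- rowSums(matrix(K[cbind(as.vector(words), rep(seq_len(L), each = nrow(words)))],
                       nrow(words)))
  pr <- apply(matrix(background[as.vector(words)], nrow(words)), 1, prod)
  sum(pr[sc >= cutoff])
}

# closed-form Pearson chi-squared for a 2x2 table (oracle, not chisq.test)
pearson_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
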