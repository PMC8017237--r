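#' TFBS scan configuration
#'
#' @param p_threshold Per-window match p-value cutoff (default 1e-4, the
#'   FIMO default).
#' @param flank Flank, nt each side of a cytosine, for CpG-neighborhood
#'   scans (default 50).
#' @param bin_width Log-odds discretization bin (log2 units) for the exact
#'   p-value dynamic program (default 1e-3).
#' @return list of class \code{tfbs_config}.
#' @export
tfbs_config <- function(p_threshold = 1e-4, flank = 50L, bin_width = 1e-3) {
  stopifnot(p_threshold > 0, p_threshold < 1, flank >= 0, bin_width > 0)
  structure(list(p_threshold = p_threshold, flank = as.integer(flank),
                 bin_width = bin_width), class = "tfbs_config")
}

BASES <- c("A", "C", "G", "T")

# as.character() drops the names of a plain character vector; keep them
#' @keywords internal
as_char_seqs <- function(x) {
  nm <- names(x)
  out <- as.character(x)
  names(out) <- nm
  out
}

#' 0-order background from sequences
#'
#' Nucleotide frequencies pooled over the given sequences and symmetrized
#' with the reverse complement, so forward and reverse scans share one
#' null score distribution.
#'
#' @param seqs Character vector of sequences (or DNAStringSet).
#' @return Named probability 4-vector (A, C, G, T).
#' @export
background_frequencies <- function(seqs) {
  seqs <- as_char_seqs(seqs)
  counts <- colSums(t(vapply(seqs, function(s) {
    v <- strsplit(toupper(s), "")[[1]]
    vapply(BASES, function(b) sum(v == b), 0)
  }, numeric(4))))
  counts <- counts + rev(counts)      # strand symmetrization (A<->T, C<->G)
  if (sum(counts) == 0) return(stats::setNames(rep(0.25, 4), BASES))
  stats::setNames(counts / sum(counts), BASES)
}

#' Discretized log-odds score matrix
#'
#' log2(P_pwm / P_background) per base and motif column, rounded to integer
#' multiples of \code{bin_width}. Scanning and the exact p-value dynamic
#' program both use this integer matrix, so match p-values are exact with
#' respect to the scored (discretized) statistic.
#'
#' @param pwm A \code{pwm}.
#' @param background Named base-probability 4-vector.
#' @param bin_width Discretization bin in log2 units.
#' @return Integer 4 x L matrix of binned log-odds scores.
#' @export
pwm_score_matrix <- function(pwm, background, bin_width = 1e-3) {
  stopifnot(abs(sum(background) - 1) < 1e-9, all(background > 0))
  probs <- pmax(pwm$probs, 1e-10)     # keep log-odds finite at hard zeros
  lo <- log2(probs / background[BASES])
  K <- round(lo / bin_width)
  storage.mode(K) <- "integer"
  rownames(K) <- BASES
  K
}

#' Exact null distribution of the PWM score
#'
#' Dynamic program over motif columns: the distribution of the integer
#' (binned) score of a random word drawn from the 0-order background.
#'
#' @param K Integer score matrix from \code{pwm_score_matrix}.
#' @param background Named base-probability 4-vector.
#' @return list: \code{score} (integer grid from min to max attainable),
#'   \code{prob} (point masses), \code{tail} (P(score >= s), same grid).
#' @export
pwm_score_distribution <- function(K, background) {
  b <- background[BASES]
  cur_lo <- 0L
  cur <- 1                             # point mass at score 0 before any column
  for (j in seq_len(ncol(K))) {
    new_lo <- cur_lo + min(K[, j])
    new_len <- length(cur) + (max(K[, j]) - min(K[, j]))
    new <- numeric(new_len)
    for (base in 1:4) {
      sh <- K[base, j] - min(K[, j])
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + b[base] * cur
    }
    cur <- new
    cur_lo <- new_lo
  }
  score <- seq.int(cur_lo, cur_lo + length(cur) - 1L)
  tail <- rev(cumsum(rev(cur)))
  list(score = score, prob = cur, tail = tail)
}

#' Minimal score achieving a p-value below threshold
#'
#' @param dist Output of \code{pwm_score_distribution}.
#' @param p_threshold Match p-value cutoff.
#' @return Integer score threshold, or NA if no attainable score is
#'   significant at the threshold.
#' @keywords internal
score_cutoff <- function(dist, p_threshold) {
  i <- which(dist$tail < p_threshold)
  if (!length(i)) return(NA_integer_)
  dist$score[i[1]]
}

#' @keywords internal
encode_seq <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  bad <- setdiff(unique(v), c(BASES, "N"))
  if (length(bad))
    stop("invalid alphabet character(s): ", paste(bad, collapse = ", "))
  match(v, BASES)                      # N -> NA
}

#' @keywords internal
revcomp_score_matrix <- function(K) {
  K[4:1, ncol(K):1, drop = FALSE]
}

#' @keywords internal
window_scores <- function(x, K) {
  L <- ncol(K)
  nw <- length(x) - L + 1L
  if (nw < 1L) return(integer(0))
  S <- integer(nw)
  for (j in seq_len(L))
    S <- S + K[, j][x[j:(j + nw - 1L)]]
  S                                    # NA where window contains N
}

#' Scan sequences with a PWM
#'
#' FIMO-style scan: the log-odds score against a 0-order background is
#' computed for every window on both strands, and windows whose exact
#' p-value (probability of an equal or higher score under the background)
#' is below the threshold are reported. Windows containing N are skipped;
#' a motif longer than the sequence yields no matches.
#'
#' @param seqs Named character vector (or DNAStringSet) of sequences over
#'   A, C, G, T, N.
#' @param pwm A \code{pwm}.
#' @param cfg A \code{tfbs_config}.
#' @param background NULL to estimate 0-order frequencies from \code{seqs}
#'   (default), or a named 4-vector (e.g. uniform).
#' @return data.frame: seq_id, pos (1-based window start on the forward
#'   strand), strand, score (log2 odds), p.
#' @export
scan_sequences <- function(seqs, pwm, cfg = tfbs_config(), background = NULL) {
  seqs <- as_char_seqs(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (is.null(background)) background <- background_frequencies(seqs)
  K <- pwm_score_matrix(pwm, background, cfg$bin_width)
  dist <- pwm_score_distribution(K, background)
  cut <- score_cutoff(dist, cfg$p_threshold)
  Krc <- revcomp_score_matrix(K)
  L <- ncol(K)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    x <- encode_seq(seqs[i])
    hits <- list()
    for (str in c("+", "-")) {
      S <- window_scores(x, if (str == "+") K else Krc)
      keep <- which(!is.na(S) & !is.na(cut) & S >= cut)
      if (length(keep))
        hits[[str]] <- data.frame(seq_id = names(seqs)[i], pos = keep,
                                  strand = str,
                                  score = S[keep] * cfg$bin_width,
                                  p = dist$tail[match(S[keep], dist$score)])
    }
    out[[i]] <- if (length(hits)) do.call(rbind, hits) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(seq_id = character(), pos = integer(),
                      strand = character(), score = numeric(), p = numeric())
  rownames(res) <- NULL
  res
}

#' Per-motif enrichment of foreground vs outgroup sequences
#'
#' For each motif, sequences with at least one significant match are
#' counted in the foreground and the outgroup, a Pearson chi-squared test
#' (no continuity correction) is applied to the 2x2 table, and p-values are
#' BH-corrected across motifs. A log2 fold-change of hit proportions
#' (Haldane 0.5 correction on the 2x2 cells) gives the direction.
#'
#' @param fg,bg Named character vectors of foreground / outgroup sequences
#'   (disjoint, each non-empty).
#' @param pwms List of \code{pwm} objects.
#' @param cfg A \code{tfbs_config}.
#' @param unit "sequences" (default: binarized per sequence) or "matches"
#'   (total match counts vs scanned windows).
#' @param background NULL to estimate from fg + bg jointly, or a 4-vector.
#' @return data.frame per motif: fg_hits, fg_total, bg_hits, bg_total,
#'   log2fc, chi2, p, q, note (reason when the test is undefined).
#' @export
motif_enrichment <- function(fg, bg, pwms, cfg = tfbs_config(),
                             unit = c("sequences", "matches"),
                             background = NULL) {
  unit <- match.arg(unit)
  fg <- as_char_seqs(fg)
  bg <- as_char_seqs(bg)
  if (!length(fg) || !length(bg)) stop("fg and bg must both be non-empty")
  if (is.null(names(fg))) names(fg) <- paste0("fg", seq_along(fg))
  if (is.null(names(bg))) names(bg) <- paste0("bg", seq_along(bg))
  if (length(intersect(names(fg), names(bg))))
    stop("fg and bg sequence sets must be disjoint")
  if (is.null(background)) background <- background_frequencies(c(fg, bg))
  rows <- lapply(pwms, function(pwm) {
    hf <- scan_sequences(fg, pwm, cfg, background)
    hb <- scan_sequences(bg, pwm, cfg, background)
    if (unit == "sequences") {
      fg_hits <- length(unique(hf$seq_id)); fg_total <- length(fg)
      bg_hits <- length(unique(hb$seq_id)); bg_total <- length(bg)
    } else {
      L <- ncol(pwm$probs)
      fg_hits <- nrow(hf)
      fg_total <- sum(pmax(nchar(fg) - L + 1L, 0L)) * 2L
      bg_hits <- nrow(hb)
      bg_total <- sum(pmax(nchar(bg) - L + 1L, 0L)) * 2L
    }
    tab <- rbind(c(fg_hits, fg_total - fg_hits),
                 c(bg_hits, bg_total - bg_hits))
    note <- NA_character_
    chi2 <- p <- NA_real_
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      note <- "zero margin: chi-squared undefined"
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chi2 <- unname(ct$statistic)
      p <- ct$p.value
    }
    log2fc <- log2(((fg_hits + 0.5) / (fg_total + 1)) /
                     ((bg_hits + 0.5) / (bg_total + 1)))
    data.frame(motif_id = pwm$motif_id, fg_hits = fg_hits, fg_total = fg_total,
               bg_hits = bg_hits, bg_total = bg_total, log2fc = log2fc,
               chi2 = chi2, p = p, note = note)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, "BH")
  rownames(res) <- NULL
  res[, c("motif_id", "fg_hits", "fg_total", "bg_hits", "bg_total",
          "log2fc", "chi2", "p", "q", "note")]
}

#' Extract flanking windows around cytosines
#'
#' The window is [pos - flank, pos + flank - 1] in 1-based coordinates
#' (length 2 x flank), truncated at chromosome ends with a flag.
#'
#' @param sites data.frame with chrom, pos (1-based).
#' @param genome Named character vector or DNAStringSet of chromosome
#'   sequences.
#' @param flank Flank width each side (default 50).
#' @return list: \code{seqs} (named character vector), \code{truncated}
#'   (logical).
#' @export
extract_flanks <- function(sites, genome, flank = 50L) {
  genome <- as_char_seqs(genome)
  unknown <- setdiff(unique(sites$chrom), names(genome))
  if (length(unknown))
    stop("site(s) on unknown chromosome: ", paste(unknown, collapse = ", "))
  clen <- nchar(genome)[sites$chrom]
  start <- sites$pos - flank
  end <- sites$pos + flank - 1L
  truncated <- start < 1L | end > clen
  start <- pmax(start, 1L)
  end <- pmin(end, clen)
  seqs <- substr(genome[sites$chrom], start, end)
  names(seqs) <- sprintf("%s:%d", sites$chrom, sites$pos)
  list(seqs = seqs, truncated = truncated)
}

#' Motif enrichment in CpG flanking windows
#'
#' Scans the 100-bp neighborhoods (default: 50 bp each side) of
#' differentially methylated promoter cytosines against the neighborhoods
#' of non-differentially methylated promoter cytosines as outgroup,
#' with the same per-motif chi-squared + BH machinery as
#' \code{motif_enrichment}.
#'
#' @param dm_sites,non_dm_sites data.frames with chrom, pos.
#' @param genome Named chromosome sequences.
#' @param pwms List of \code{pwm} objects.
#' @param cfg A \code{tfbs_config}.
#' @return As \code{motif_enrichment}.
#' @export
cpg_flank_enrichment <- function(dm_sites, non_dm_sites, genome, pwms,
                                 cfg = tfbs_config()) {
  fg <- extract_flanks(dm_sites, genome, cfg$flank)$seqs
  bg <- extract_flanks(non_dm_sites, genome, cfg$flank)$seqs
  names(fg) <- paste0("dm_", names(fg))
  names(bg) <- paste0("ndm_", names(bg))
  motif_enrichment(fg, bg, pwms, cfg)
}
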