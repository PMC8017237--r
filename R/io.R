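#' Read a gene-level count matrix
#'
#' Expects a TSV with a \code{gene_id} first column and one column per sample
#' in the design. Columns are re-ordered to match the design; library sizes
#' are the raw column sums.
#'
#' @param path Path to the counts TSV.
#' @param design A \code{sample_design}.
#' @return An \code{edgeR::DGEList} with \code{samples$lib.size} set to the
#'   column sums and all normalization factors 1.
#' @export
read_counts <- function(path, design) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(x)[1] != "gene_id")
    stop("counts file must have 'gene_id' as first column")
  missing <- setdiff(design$sample_id, names(x))
  if (length(missing))
    stop("counts file lacks sample column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(x$gene_id))
    stop("duplicate gene id(s): ",
         paste(unique(x$gene_id[duplicated(x$gene_id)]), collapse = ", "))
  m <- as.matrix(x[, design$sample_id, drop = FALSE])
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  rownames(m) <- x$gene_id
  storage.mode(m) <- "integer"
  edgeR::DGEList(counts = m, group = design$group)
}

#' Write a count matrix to TSV
#'
#' @param counts Matrix (genes x samples) or a DGEList.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  if (inherits(counts, "DGEList")) counts <- counts$counts
  out <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a per-cytosine methylation matrix
#'
#' The container used for RRBS and oxRRBS counts: a site table plus matched
#' methylated/total count matrices (sites x samples).
#'
#' @param sites data.frame with columns chrom, pos (1-based cytosine
#'   position), strand, context ("CpG"/"CpH").
#' @param meth,total Integer matrices, one row per site, columns named by
#'   sample id.
#' @param assay "rrbs" or "oxrrbs".
#' @return A list of class \code{meth_mat}.
#' @export
meth_matrix <- function(sites, meth, total, assay = c("rrbs", "oxrrbs")) {
  assay <- match.arg(assay)
  stopifnot(nrow(sites) == nrow(meth), nrow(sites) == nrow(total),
            identical(dim(meth), dim(total)), identical(colnames(meth), colnames(total)))
  if (!all(sites$context %in% c("CpG", "CpH")))
    stop("unknown context token(s): ",
         paste(setdiff(unique(sites$context), c("CpG", "CpH")), collapse = ", "))
  bad <- which(meth > total, arr.ind = TRUE)
  if (nrow(bad))
    stop("meth > total at site row ", bad[1, 1], ", sample ", colnames(meth)[bad[1, 2]])
  key <- site_key(sites)
  if (anyDuplicated(key))
    stop("duplicate site(s): ", key[duplicated(key)][1])
  rownames(sites) <- rownames(meth) <- rownames(total) <- key
  structure(list(sites = sites, meth = meth, total = total, assay = assay),
            class = "meth_mat")
}

#' @keywords internal
site_key <- function(sites) {
  paste(sites$chrom, sites$pos, sites$strand, sites$context, sep = ":")
}

#' @export
print.meth_mat <- function(x, ...) {
  cat(sprintf("meth_mat: %d sites x %d samples (%s; %d CpG, %d CpH)\n",
              nrow(x$sites), ncol(x$meth), x$assay,
              sum(x$sites$context == "CpG"), sum(x$sites$context == "CpH")))
  invisible(x)
}

#' Read a per-cytosine report
#'
#' Long-format TSV, one row per (site, sample): columns chrom, pos, strand,
#' context, sample_id, meth, total. This is the package's own on-disk
#' dialect of a Bismark-style cytosine report (documented in the README).
#' Sites absent for a sample get total = 0 (no coverage).
#'
#' @param path Path to the TSV.
#' @param design A \code{sample_design}; per-sample columns are aligned to it.
#' @param assay "rrbs" or "oxrrbs".
#' @return A \code{meth_mat}.
#' @export
read_cytosine_report <- function(path, design, assay = c("rrbs", "oxrrbs")) {
  assay <- match.arg(assay)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "context", "sample_id", "meth", "total")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("cytosine report lacks column(s): ", paste(missing, collapse = ", "))
  if (any(x$meth > x$total))
    stop("meth > total in cytosine report (first offending row ",
         which(x$meth > x$total)[1], ")")
  unknown <- setdiff(unique(x$sample_id), design$sample_id)
  if (length(unknown))
    stop("cytosine report has sample(s) not in design: ",
         paste(unknown, collapse = ", "))
  skey <- paste(x$chrom, x$pos, x$strand, x$context, sep = ":")
  usites <- !duplicated(skey)
  sites <- x[usites, c("chrom", "pos", "strand", "context")]
  n <- nrow(sites)
  p <- nrow(design)
  meth <- total <- matrix(0L, n, p, dimnames = list(skey[usites], design$sample_id))
  i <- match(skey, skey[usites])
  j <- match(x$sample_id, design$sample_id)
  idx <- cbind(i, j)
  if (anyDuplicated(idx))
    stop("duplicate (site, sample) row in cytosine report")
  meth[idx] <- as.integer(x$meth)
  total[idx] <- as.integer(x$total)
  meth_matrix(sites, meth, total, assay)
}

#' Write a per-cytosine report
#'
#' Inverse of \code{read_cytosine_report}; rows with total = 0 are omitted
#' (no coverage is encoded by absence).
#'
#' @param m A \code{meth_mat}.
#' @param path Output path.
#' @export
write_cytosine_report <- function(m, path) {
  idx <- which(m$total > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(m$sites[idx[, 1], c("chrom", "pos", "strand", "context")],
                    sample_id = colnames(m$total)[idx[, 2]],
                    meth = m$meth[idx], total = m$total[idx],
                    row.names = NULL)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Chromosome class from chromosome name
#'
#' Z and autosomal fragments whose exact placement is unknown carry a
#' \code{_random} suffix in the Ensembl annotation; they are labeled
#' \code{random_Z} / \code{random_autosome} and downstream dosage analyses
#' merge them into their parent class.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector over {autosome, Z, W, random_autosome, random_Z}.
#' @export
chrom_class <- function(chrom) {
  base <- sub("_random$", "", chrom)
  is_random <- grepl("_random$", chrom)
  cls <- ifelse(base == "Z", "Z", ifelse(base == "W", "W", "autosome"))
  cls[is_random & cls == "Z"] <- "random_Z"
  cls[is_random & cls == "autosome"] <- "random_autosome"
  cls
}

#' Read gene annotation from GTF
#'
#' Imports gene features from a GTF (1-based inclusive coordinates, kept
#' as-is internally) and derives the strand-aware TSS and chromosome class.
#' A \code{tf} attribute, if present in the GTF, sets the transcription
#' factor flag.
#'
#' @param path Path to a GTF file with \code{gene} features.
#' @return data.frame with columns gene_id, chrom, start, end, strand, tss,
#'   chrom_class, is_tf.
#' @export
read_annotation <- function(path) {
  g <- rtracklayer::import(path, format = "gtf")
  g <- g[g$type == "gene"]
  if (!length(g)) stop("no gene features in GTF: ", path)
  strand <- as.character(GenomicRanges::strand(g))
  if (any(strand == "*")) stop("gene without strand in GTF")
  ann <- data.frame(
    gene_id = g$gene_id,
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    strand = strand,
    stringsAsFactors = FALSE)
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  ann$chrom_class <- chrom_class(ann$chrom)
  ann$is_tf <- if (!is.null(g$tf)) as.logical(g$tf) %in% TRUE else FALSE
  rownames(ann) <- ann$gene_id
  ann
}

#' Write gene annotation as GTF
#'
#' @param ann Annotation data.frame as from \code{read_annotation}.
#' @param path Output path.
#' @export
write_annotation_gtf <- function(ann, path) {
  attrs <- sprintf('gene_id "%s"; tf "%s";', ann$gene_id,
                   ifelse(ann$is_tf, "TRUE", "FALSE"))
  lines <- sprintf("%s\tfinchdev\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   ann$chrom, ann$start, ann$end, ann$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read position frequency matrices
#'
#' Supports JASPAR .pfm (including the bracketed 2016+ flavor) and MEME
#' minimal format. Columns are normalized to probabilities after adding a
#' pseudocount.
#'
#' @param path Path to the motif file.
#' @param pseudocount Added to every count before column normalization.
#' @return A named list of \code{pwm} objects, each a list with
#'   \code{motif_id}, \code{probs} (4 x L, rows A,C,G,T) and
#'   \code{pseudocount}.
#' @export
read_pfm <- function(path, pseudocount = 0.1) {
  lines <- readLines(path)
  if (any(grepl("^MEME version", lines))) {
    return(parse_meme_minimal(lines, pseudocount))
  }
  parse_jaspar_pfm(lines, pseudocount)
}

#' @keywords internal
parse_jaspar_pfm <- function(lines, pseudocount) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no motif headers ('>') in .pfm file")
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    id <- strsplit(sub("^>\\s*", "", lines[hdr[k]]), "\\s+")[[1]][1]
    body <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) != 4)
      stop("motif ", id, ": expected 4 rows (A,C,G,T), got ", length(body))
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]?\\s*\\[|\\]", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1) stop("motif ", id, ": ragged rows")
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[id]] <- new_pwm(id, counts, pseudocount)
  }
  out
}

#' @keywords internal
parse_meme_minimal <- function(lines, pseudocount) {
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF", lines[i])) {
      id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) && !grepl("letter-probability matrix", lines[j]))
        j <- j + 1L
      if (j > length(lines)) stop("motif ", id, ": no letter-probability matrix")
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      nsites <- if (grepl("nsites=", lines[j]))
        as.numeric(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[j])) else 100
      rows <- lines[(j + 1L):(j + w)]
      probs <- t(vapply(rows, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                        numeric(4)))
      counts <- t(probs) * nsites   # back to pseudo-counts; columns = positions
      rownames(counts) <- c("A", "C", "G", "T")
      out[[id]] <- new_pwm(id, counts, pseudocount)
      i <- j + w + 1L
    } else i <- i + 1L
  }
  if (!length(out)) stop("no MOTIF blocks in MEME file")
  out
}

#' @keywords internal
new_pwm <- function(id, counts, pseudocount) {
  if (nrow(counts) != 4) stop("motif ", id, ": matrix must have 4 rows")
  if (any(counts < 0)) stop("motif ", id, ": negative counts")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  cs <- colSums(counts)
  if (pseudocount == 0 && any(cs == 0))
    stop("motif ", id, ": column summing to 0 with zero pseudocount")
  counts <- counts + pseudocount
  probs <- sweep(counts, 2, colSums(counts), "/")
  structure(list(motif_id = id, probs = probs, pseudocount = pseudocount),
            class = "pwm")
}

#' Construct a PWM from a count (or probability) matrix
#'
#' @param id Motif identifier.
#' @param counts 4 x L non-negative matrix, rows A, C, G, T.
#' @param pseudocount Added before column normalization (default 0.1).
#' @return A \code{pwm}.
#' @export
make_pwm <- function(id, counts, pseudocount = 0.1) {
  new_pwm(id, counts, pseudocount)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: length %d, consensus %s\n", x$motif_id,
              ncol(x$probs), pwm_consensus(x)))
  invisible(x)
}

#' PWM consensus sequence
#'
#' @param pwm A \code{pwm}.
#' @return Character scalar: the argmax base per column.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$probs)[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Write a signed-significance methylation bedGraph
#'
#' UCSC bedGraph (0-based half-open; 1 bp per cytosine) encoding both the
#' methylation level and the test outcome in one track: significant sites
#' are written as +beta, non-significant sites as -max(beta, 0.001), so the
#' sign always encodes significance (the 0.001 floor keeps a beta of 0
#' distinguishable from a significant 0).
#'
#' @param sites data.frame with columns chrom, pos (1-based), beta in [0,1],
#'   significant (logical).
#' @param path Output path.
#' @param track_name Track line name attribute.
#' @return The path, invisibly.
#' @export
write_methylation_bedgraph <- function(sites, path, track_name = "methylation") {
  if (any(sites$beta < 0 | sites$beta > 1 | is.na(sites$beta)))
    stop("beta values must lie in [0, 1]")
  value <- ifelse(sites$significant, sites$beta, -pmax(sites$beta, 0.001))
  lines <- c(sprintf('track type=bedGraph name="%s"', track_name),
             sprintf("%s\t%d\t%d\t%s", sites$chrom, sites$pos - 1L, sites$pos,
                     format(value, trim = TRUE, scientific = FALSE)))
  writeLines(lines, path)
  invisible(path)
}
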