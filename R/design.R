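#' Construct the sample design table
#'
#' Builds the age x sex x pool factorial design used by every analysis stage.
#' The default reproduces the full study layout: 4 ages (1, 20, 65 days post
#' hatching and adult) x 2 sexes x 3 pooled biological replicates = 24
#' samples, each "sample" being a pool of three telencephalons.
#'
#' @param ages Character vector of age levels, in developmental order.
#' @param sexes Character vector of sex levels.
#' @param n_pools Number of pooled replicates per age x sex cell.
#' @param pool_size Number of individuals pooled per sample (metadata only).
#' @return A data.frame of class \code{sample_design} with columns
#'   \code{sample_id}, \code{age} (ordered factor), \code{sex} (factor),
#'   \code{pool} (integer), \code{pool_size}, and a derived \code{group}
#'   factor (age.sex interaction) used as the model parameterization.
#' @export
sample_design <- function(ages = c("d1", "d20", "d65", "adult"),
                          sexes = c("M", "F"),
                          n_pools = 3L,
                          pool_size = 3L) {
  stopifnot(length(ages) >= 1, length(sexes) >= 1, n_pools >= 1, pool_size >= 1)
  d <- expand.grid(pool = seq_len(n_pools), sex = sexes, age = ages,
                   stringsAsFactors = FALSE)
  d <- d[, c("age", "sex", "pool")]
  d$age <- factor(d$age, levels = ages, ordered = TRUE)
  d$sex <- factor(d$sex, levels = sexes)
  d$sample_id <- sprintf("%s_%s_p%d", as.character(d$age), as.character(d$sex), d$pool)
  d$pool_size <- as.integer(pool_size)
  d$group <- design_group(d)
  rownames(d) <- d$sample_id
  d <- d[, c("sample_id", "age", "sex", "pool", "pool_size", "group")]
  class(d) <- c("sample_design", "data.frame")
  validate_design(d)
  d
}

#' @keywords internal
design_group <- function(design) {
  factor(paste(as.character(design$age), as.character(design$sex), sep = "."),
         levels = as.vector(t(outer(levels(design$age), levels(design$sex),
                                    paste, sep = "."))))
}

#' Validate a sample design
#'
#' Checks uniqueness of sample ids and that every age x sex cell is occupied.
#'
#' @param design A \code{sample_design} data.frame.
#' @return The design, invisibly, or an error.
#' @export
validate_design <- function(design) {
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]), collapse = ", "))
  tab <- table(design$age, design$sex)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(rownames(tab)[empty[, 1]], colnames(tab)[empty[, 2]],
               sep = "/", collapse = ", "))
  }
  invisible(design)
}

#' Read a sample design from TSV
#'
#' @param path TSV with columns sample_id, age, sex, pool, pool_size.
#' @param ages,sexes Level orderings imposed on the factors.
#' @return A \code{sample_design} data.frame.
#' @export
read_design <- function(path, ages = c("d1", "d20", "d65", "adult"),
                        sexes = c("M", "F")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "sex", "pool", "pool_size")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("design file lacks column(s): ", paste(missing, collapse = ", "))
  d$age <- factor(d$age, levels = ages, ordered = TRUE)
  d$sex <- factor(d$sex, levels = sexes)
  d$group <- design_group(d)
  rownames(d) <- d$sample_id
  class(d) <- c("sample_design", "data.frame")
  validate_design(d)
  d
}

#' Write a sample design to TSV
#'
#' @param design A \code{sample_design}.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design[, c("sample_id", "age", "sex", "pool", "pool_size")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
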