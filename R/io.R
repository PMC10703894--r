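# Readers and writers for the external formats the pipeline touches:
# bismark-style CpG coverage files, BED6 intervals, gene/DE tables, FASTA.
# Inputs are converted to 0-based half-open coordinates on the way in and
# back to each dialect's convention on the way out. Files ending in ".gz"
# are read transparently.

maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else path
}

field_counts <- function(path) {
  con <- maybe_gz(path)
  utils::count.fields(con, comment.char = "")
}

#' Read a CpG methylation coverage file
#'
#' Parses a per-sample CpG coverage file into a data frame of per-CpG
#' methylated/unmethylated read counts. The default dialect is the bismark
#' coverage format (`chrom start end pct_methylated count_methylated
#' count_unmethylated`, 1-based inclusive positions); the percentage column
#' is ignored in favour of the counts. A `plain` dialect
#' (`chrom pos0 count_methylated count_unmethylated`, 0-based) is also
#' supported.
#'
#' Rows with zero total coverage are retained (coverage 0 at that CpG).
#' Unsorted input is sorted with a warning; duplicated positions within a
#' chromosome are an error.
#'
#' @param path Path to the coverage file (optionally gzipped).
#' @param sample_id Optional sample label stored as an attribute.
#' @param dialect `"bismark"` (default) or `"plain"`.
#' @return A data frame with columns `chrom`, `pos` (0-based position of the
#'   C of the CpG), `meth`, `unmeth`.
#' @export
read_coverage <- function(path, sample_id = NULL,
                          dialect = c("bismark", "plain")) {
  dialect <- match.arg(dialect)
  ncol_exp <- if (dialect == "bismark") 6L else 4L
  nf <- field_counts(path)
  out_empty <- data.frame(chrom = character(), pos = integer(),
                          meth = integer(), unmeth = integer(),
                          stringsAsFactors = FALSE)
  if (length(nf) == 0) {
    attr(out_empty, "sample_id") <- sample_id
    return(out_empty)
  }
  bad <- which(nf != ncol_exp)
  if (length(bad))
    stop(sprintf("malformed coverage row at line %d of %s: expected %d fields, found %d",
                 bad[1], path, ncol_exp, nf[bad[1]]), call. = FALSE)
  df <- utils::read.table(maybe_gz(path), header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (dialect == "bismark") {
    out <- data.frame(chrom = as.character(df[[1]]),
                      pos = as.integer(df[[2]]) - 1L,
                      meth = as.integer(df[[5]]),
                      unmeth = as.integer(df[[6]]),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chrom = as.character(df[[1]]),
                      pos = as.integer(df[[2]]),
                      meth = as.integer(df[[3]]),
                      unmeth = as.integer(df[[4]]),
                      stringsAsFactors = FALSE)
  }
  if (any(is.na(out$pos) | is.na(out$meth) | is.na(out$unmeth)))
    stop("non-numeric position or count in ", path, call. = FALSE)
  if (any(out$meth < 0 | out$unmeth < 0))
    stop("negative read count in ", path, call. = FALSE)
  ord <- order(out$chrom, out$pos)
  if (is.unsorted(ord) || any(ord != seq_along(ord))) {
    warning("coverage file ", path, " is not position-sorted; sorting",
            call. = FALSE)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  dup <- which(duplicated(paste(out$chrom, out$pos)))
  if (length(dup))
    stop(sprintf("duplicate CpG position %s:%d in %s", out$chrom[dup[1]],
                 out$pos[dup[1]], path), call. = FALSE)
  attr(out, "sample_id") <- sample_id
  out
}

#' Write a CpG coverage file
#'
#' Inverse of [read_coverage()]. In the bismark dialect positions are
#' written 1-based inclusive with the percent-methylated column derived
#' from the counts (0 for uncovered CpGs). All rows are written, including
#' zero-coverage CpGs, so that a set of per-sample files shares one
#' position universe and `write(read(x))` is lossless.
#'
#' @param df Data frame with columns `chrom`, `pos`, `meth`, `unmeth`.
#' @param path Output path.
#' @param dialect `"bismark"` or `"plain"`.
#' @export
write_coverage <- function(df, path, dialect = c("bismark", "plain")) {
  dialect <- match.arg(dialect)
  if (dialect == "bismark") {
    cov <- df$meth + df$unmeth
    pct <- ifelse(cov > 0, 100 * df$meth / cov, 0)
    lines <- paste(df$chrom, df$pos + 1L, df$pos + 1L,
                   as.character(pct), df$meth, df$unmeth, sep = "\t")
  } else {
    lines <- paste(df$chrom, df$pos, df$meth, df$unmeth, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Merge per-sample CpG coverage into a multi-sample matrix
#'
#' Takes per-sample coverage data frames (as returned by [read_coverage()])
#' and merges them over the union of CpG positions. CpGs absent from a
#' sample's file get coverage 0 in that sample rather than being dropped,
#' so downstream per-sample coverage filters see every position.
#'
#' @param cov_list Named list of coverage data frames (names are sample ids),
#'   or unnamed with `sample_ids` supplied.
#' @param sample_ids Optional character vector of sample ids.
#' @return An object of class `cpg_matrix`: a list with `chrom`, `pos`
#'   (0-based, sorted), integer matrices `meth` and `cov` (CpG x sample),
#'   and `samples`.
#' @export
merge_coverage <- function(cov_list, sample_ids = names(cov_list)) {
  if (is.null(sample_ids) || any(!nzchar(sample_ids)))
    stop("sample ids are required to merge coverage", call. = FALSE)
  keys <- unique(do.call(rbind, lapply(cov_list, function(d) d[c("chrom", "pos")])))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  key_str <- paste(keys$chrom, keys$pos)
  n <- nrow(keys); s <- length(cov_list)
  meth <- matrix(0L, n, s, dimnames = list(NULL, sample_ids))
  cov <- matrix(0L, n, s, dimnames = list(NULL, sample_ids))
  for (j in seq_len(s)) {
    d <- cov_list[[j]]
    i <- match(paste(d$chrom, d$pos), key_str)
    meth[i, j] <- d$meth
    cov[i, j] <- d$meth + d$unmeth
  }
  new_cpg_matrix(keys$chrom, keys$pos, meth, cov, sample_ids)
}

new_cpg_matrix <- function(chrom, pos, meth, cov, samples) {
  stopifnot(length(chrom) == length(pos), nrow(meth) == length(pos),
            all(dim(meth) == dim(cov)))
  if (any(meth > cov)) stop("methylated count exceeds coverage", call. = FALSE)
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 meth = meth, cov = cov, samples = samples),
            class = "cpg_matrix")
}

#' @export
print.cpg_matrix <- function(x, ...) {
  cat(sprintf("cpg_matrix: %d CpGs on %d chromosome(s), %d sample(s)\n",
              length(x$pos), length(unique(x$chrom)), length(x$samples)))
  invisible(x)
}

# one sample of a cpg_matrix as a coverage data frame
cpg_sample_frame <- function(cpg, sample) {
  j <- match(sample, cpg$samples)
  if (is.na(j)) stop("unknown sample: ", sample, call. = FALSE)
  data.frame(chrom = cpg$chrom, pos = cpg$pos, meth = cpg$meth[, j],
             unmeth = cpg$cov[, j] - cpg$meth[, j], stringsAsFactors = FALSE)
}

#' Read a BED file of genomic intervals
#'
#' BED coordinates are 0-based half-open and are passed through unchanged.
#' Columns beyond the first three are optional; missing `name`/`strand` are
#' `NA`, and a literal `"."` score is read as `NA`.
#'
#' @param path Path to a BED file (>= 3 columns, optionally gzipped).
#' @return Data frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  nf <- field_counts(path)
  if (length(nf) == 0) return(empty_intervals())
  short <- which(nf < 3)
  if (length(short))
    stop(sprintf("BED row with fewer than 3 fields at line %d of %s",
                 short[1], path), call. = FALSE)
  df <- utils::read.table(maybe_gz(path), header = FALSE, fill = TRUE,
                          stringsAsFactors = FALSE, comment.char = "",
                          colClasses = "character")
  out <- data.frame(chrom = df[[1]], start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  out$name <- if (ncol(df) >= 4) df[[4]] else NA_character_
  out$score <- if (ncol(df) >= 5) {
    suppressWarnings(ifelse(df[[5]] == ".", NA_real_, as.numeric(df[[5]])))
  } else NA_real_
  out$strand <- if (ncol(df) >= 6) df[[6]] else NA_character_
  bad <- which(!(out$start < out$end))
  if (length(bad))
    stop(sprintf("invalid interval (start >= end) at line %d of %s",
                 bad[1], path), call. = FALSE)
  out
}

#' Write intervals as BED
#'
#' Writes 6 columns when any of `name`, `score`, `strand` is present,
#' otherwise 3. `NA` name/strand and `NA` score are written as `"."`.
#'
#' @param df Interval data frame (0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df, "BED interval")
  has_extra <- any(!is.na(df$name)) || any(!is.na(df$score)) ||
    any(!is.na(df$strand))
  if (nrow(df) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (has_extra) {
    nm <- ifelse(is.na(df$name), ".", df$name)
    sc <- ifelse(is.na(df$score), ".", as.character(df$score))
    st <- ifelse(is.na(df$strand), ".", df$strand)
    lines <- paste(df$chrom, df$start, df$end, nm, sc, st, sep = "\t")
  } else {
    lines <- paste(df$chrom, df$start, df$end, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Requires columns `gene_id`, `log2fc`, `pvalue`; `qvalue` is optional and
#' its absence is recorded in the `has_qvalue` attribute so callers can
#' apply Benjamini-Hochberg correction downstream.
#'
#' @param path Path to a TSV with a header row.
#' @return Data frame of DE results.
#' @export
read_de_table <- function(path) {
  df <- utils::read.table(maybe_gz(path), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("gene_id", "log2fc", "pvalue")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("DE table ", path, " missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  attr(df, "has_qvalue") <- "qvalue" %in% names(df)
  df
}

#' Write a results table as TSV
#'
#' Plain deterministic TSV writer (header, tab-separated, no quoting) used
#' for every result table the pipeline emits.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @export
write_results_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write genome FASTA
#'
#' Thin wrappers over Biostrings; sequences are wrapped at 60 columns on
#' output.
#'
#' @param path FASTA path.
#' @return `read_fasta` returns a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs Named `DNAStringSet` (or named character vector).
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}
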