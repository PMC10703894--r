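# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open; readers/writers convert per dialect.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(1, pmax(0, x))

# 0-based half-open data.frame -> GRanges (1-based closed).
as_gr0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

new_intervals <- function(chrom, start, end, name = NA_character_,
                          score = NA_real_, strand = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), name = as.character(name),
                   score = as.numeric(score), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom) | df$chrom == ""))
    stop(what, " with empty chromosome name", call. = FALSE)
  bad <- which(!(df$start < df$end))
  if (length(bad))
    stop(sprintf("%s %d has start >= end (%d >= %d)", what, bad[1],
                 df$start[bad[1]], df$end[bad[1]]), call. = FALSE)
  invisible(df)
}

# deterministic ordering used everywhere intervals are written out
order_intervals <- function(df) df[order(df$chrom, df$start, df$end), , drop = FALSE]

# overlap helpers; disjoint chromosome sets between query and subject are a
# legitimate situation here, so the seqlevel warning is silenced
ov_count <- function(a, b)
  suppressWarnings(GenomicRanges::countOverlaps(a, b))
ov_find <- function(a, b, ...)
  suppressWarnings(GenomicRanges::findOverlaps(a, b, ...))
ov_distance <- function(a, b)
  suppressWarnings(GenomicRanges::distance(a, b))
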