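# Known-motif enrichment inside DMRs: a log-odds PWM scanner over both
# strands and an upper-tail hypergeometric test of hit-bearing probes in
# the significant-DMR foreground against the tested-probe background
# (ZOOPS counting: a probe counts once however many hits it carries).

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param motif_id Motif identifier.
#' @param mat 4 x width numeric matrix of per-column base probabilities,
#'   rows in order A, C, G, T; every column must sum to 1 (tolerance 1e-9)
#'   and the matrix must be at least 4 columns wide.
#' @param background Background base frequencies (default uniform 0.25).
#' @return An object of class `pwm`.
#' @export
make_pwm <- function(motif_id, mat, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A, C, G, T)", call. = FALSE)
  if (ncol(mat) < 4) stop("PWM must be at least 4 columns long", call. = FALSE)
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9))
    stop("PWM columns must each sum to 1", call. = FALSE)
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 frequencies summing to 1", call. = FALSE)
  rownames(mat) <- BASES
  structure(list(motif_id = motif_id, mat = mat,
                 background = stats::setNames(background, BASES)),
            class = "pwm")
}

#' Sharp PWM around a consensus sequence
#'
#' Convenience constructor: probability `p` on the consensus base at every
#' position, `(1 - p) / 3` elsewhere.
#'
#' @param motif_id Motif identifier.
#' @param consensus Consensus string over A/C/G/T.
#' @param p Probability of the consensus base (default 0.85; `p = 1` gives
#'   an exact-match-only matrix).
#' @export
consensus_pwm <- function(motif_id, consensus, p = 0.85) {
  b <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(b %in% BASES))
  mat <- matrix((1 - p) / 3, 4, length(b), dimnames = list(BASES, NULL))
  mat[cbind(match(b, BASES), seq_along(b))] <- p
  make_pwm(motif_id, mat)
}

#' Read PWMs from a JASPAR-style text file
#'
#' Minimal JASPAR format: a `>id [name]` header line followed by four rows
#' `A [ n1 n2 ... ]` (brackets optional) giving per-position counts or
#' probabilities; columns are normalised to probabilities.
#'
#' @param path Input path.
#' @return Named list of `pwm` objects.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no motif records in ", path, call. = FALSE)
  out <- list()
  for (i in seq_along(starts)) {
    id <- strsplit(sub("^>\\s*", "", lines[starts[i]]), "\\s+")[[1]][1]
    last <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    body <- lines[(starts[i] + 1):last]
    if (length(body) < 4)
      stop("motif ", id, " has fewer than 4 matrix rows", call. = FALSE)
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("[][]", " ", l)
      v <- strsplit(trimws(l), "\\s+")[[1]]
      as.numeric(v[-1])  # drop base letter
    })
    mat <- do.call(rbind, rows)
    mat <- sweep(mat, 2, colSums(mat), "/")
    out[[id]] <- make_pwm(id, mat)
  }
  out
}

# integer-encode a sequence: A=1 C=2 G=3 T=4, anything else (N) = 5
encode_seq <- function(seq) {
  if (methods::is(seq, "DNAString") || methods::is(seq, "DNAStringSet"))
    seq <- as.character(seq)
  chars <- strsplit(toupper(seq), "")[[1]]
  code <- match(chars, BASES)
  code[is.na(code)] <- 5L
  code
}

# 5 x width log2-odds matrix; 5th row (N) contributes 0
logodds_matrix <- function(pwm) {
  L <- log2(pwm$mat / pwm$background)
  rbind(L, N = 0)
}

#' Scan a sequence for PWM hits on both strands
#'
#' Scores every offset with the log2-odds of the PWM against its background
#' frequencies; a hit is an offset scoring at least `threshold_fraction`
#' times the maximum achievable score. `N` bases score as background
#' (log-odds 0). The reverse strand is scanned with the
#' reverse-complemented matrix and reported at the same forward
#' coordinates.
#'
#' @param seq Character string or `DNAString`.
#' @param pwm A `pwm` object.
#' @param threshold_fraction Fraction of the maximum score (default 0.8).
#' @param both_strands Scan the minus strand too (default TRUE).
#' @return Data frame `start` (0-based), `end` (exclusive), `strand`,
#'   `score`; zero rows when the sequence is shorter than the motif.
#' @export
scan_sequence <- function(seq, pwm, threshold_fraction = 0.8,
                          both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"), threshold_fraction > 0,
            threshold_fraction <= 1)
  code <- encode_seq(seq)
  w <- ncol(pwm$mat)
  n <- length(code)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (n < w) return(empty)
  L <- logodds_matrix(pwm)
  max_score <- sum(apply(L[1:4, , drop = FALSE], 2, max))
  thr <- threshold_fraction * max_score
  scan_one <- function(M) {
    s <- numeric(n - w + 1)
    for (j in seq_len(w)) s <- s + M[code[j:(n - w + j)], j]
    s
  }
  res <- list()
  sf <- scan_one(L)
  hit <- which(sf >= thr)
  if (length(hit))
    res[["+"]] <- data.frame(start = hit - 1L, end = hit - 1L + w,
                             strand = "+", score = sf[hit],
                             stringsAsFactors = FALSE)
  if (both_strands) {
    Lrc <- L[c(4:1, 5), rev(seq_len(w)), drop = FALSE]
    rownames(Lrc) <- c(BASES, "N")
    sr <- scan_one(Lrc)
    hit <- which(sr >= thr)
    if (length(hit))
      res[["-"]] <- data.frame(start = hit - 1L, end = hit - 1L + w,
                               strand = "-", score = sr[hit],
                               stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Upper-tail hypergeometric enrichment of motif-bearing probes
#'
#' With universe `N = |foreground| + |background|`, `K` hit-bearing probes
#' in the universe, `n` foreground probes and `k` hit-bearing foreground
#' probes, computes `P(X >= k)` for hypergeometric `X`.
#'
#' @param foreground_ids,background_ids Disjoint probe id sets (the
#'   universe is their union).
#' @param hit_ids Probe ids carrying at least one motif occurrence.
#' @return One-row data frame `k`, `n`, `K`, `N`, `pvalue`.
#' @export
hypergeometric_enrichment <- function(foreground_ids, background_ids,
                                      hit_ids) {
  if (length(foreground_ids) == 0)
    stop("empty foreground set", call. = FALSE)
  universe <- union(foreground_ids, background_ids)
  k <- sum(foreground_ids %in% hit_ids)
  K <- sum(universe %in% hit_ids)
  n <- length(foreground_ids)
  N <- length(universe)
  if (k > n) stop("more foreground hits than foreground probes", call. = FALSE)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(k = k, n = n, K = K, N = N, pvalue = p)
}

#' Motif enrichment within DMRs
#'
#' Foreground: significant DMR probes of the requested direction.
#' Background: all other tested probes of the comparison. Each PWM is
#' scanned over the genome on both strands; a probe is a hit when at least
#' one motif occurrence overlaps it. Results carry BH q-values and are
#' sorted by ascending p.
#'
#' @param calls A `dmr_calls` table.
#' @param genome Named `DNAStringSet` (or FASTA path) covering the probes'
#'   chromosomes.
#' @param pwms List of `pwm` objects.
#' @param direction `"hyper"` or `"hypo"`.
#' @param threshold_fraction Scanner threshold (default 0.8).
#' @return Data frame `motif`, `k`, `n`, `K`, `N`, `pvalue`, `qvalue`.
#' @export
enrich_dmrs <- function(calls, genome, pwms,
                        direction = c("hyper", "hypo"),
                        threshold_fraction = 0.8) {
  direction <- match.arg(direction)
  if (is.character(genome) && length(genome) == 1) genome <- read_fasta(genome)
  fg <- calls$probe_id[calls$significant & calls$direction == direction]
  bg <- setdiff(calls$probe_id, fg)
  empty <- data.frame(motif = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), pvalue = numeric(),
                      qvalue = numeric(), stringsAsFactors = FALSE)
  if (length(fg) == 0) {
    warning("no significant ", direction, "methylated DMRs", call. = FALSE)
    return(empty)
  }
  probe_gr <- as_gr0(calls)
  ids <- if (is.null(names(pwms)))
    vapply(pwms, `[[`, character(1), "motif_id") else names(pwms)
  rows <- lapply(seq_along(pwms), function(i) {
    hits_by_chrom <- lapply(names(genome), function(ch) {
      h <- scan_sequence(genome[[ch]], pwms[[i]],
                         threshold_fraction = threshold_fraction)
      if (nrow(h)) h$chrom <- ch
      h
    })
    hits <- do.call(rbind, hits_by_chrom[vapply(hits_by_chrom, nrow,
                                                integer(1)) > 0])
    hit_ids <- character(0)
    if (!is.null(hits) && nrow(hits)) {
      hgr <- GenomicRanges::GRanges(hits$chrom,
                                    IRanges::IRanges(hits$start + 1L,
                                                     hits$end))
      hit_ids <- calls$probe_id[ov_count(probe_gr, hgr) > 0]
    }
    cbind(motif = ids[i],
          hypergeometric_enrichment(fg, bg, hit_ids),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}
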