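#' @useDynLib viromeKit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# columns of the hit table, in BLAST outfmt6-like order plus coverage
.hitColumns <- c("query_id", "subject_id", "identity_percent",
                 "alignment_length", "identities", "query_start", "query_end",
                 "subject_start", "subject_end", "raw_score", "bit_score",
                 "evalue", "query_coverage_percent", "strand")

.emptyHits <- function() {
  out <- data.frame(query_id = character(), subject_id = character(),
                    identity_percent = numeric(), alignment_length = integer(),
                    identities = integer(), query_start = integer(),
                    query_end = integer(), subject_start = integer(),
                    subject_end = integer(), raw_score = numeric(),
                    bit_score = numeric(), evalue = numeric(),
                    query_coverage_percent = numeric(), strand = character(),
                    stringsAsFactors = FALSE)
  out
}

#' Default protein scoring parameters
#'
#' BLOSUM62 with gap open 11 / extend 1 and the standard gapped
#' Karlin-Altschul parameters (lambda = 0.267, K = 0.041), mirroring
#' common BLASTp defaults.
#'
#' @param gapOpen,gapExtend affine gap penalties (positive).
#' @param lambda,K Karlin-Altschul parameters.
#' @return a [ScoringParams-class] object.
#' @export
proteinScoringParams <- function(gapOpen = 11, gapExtend = 1,
                                 lambda = 0.267, K = 0.041) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  new("ScoringParams", matrix = e$BLOSUM62, gapOpen = gapOpen,
      gapExtend = gapExtend, lambda = lambda, K = K, type = "protein")
}

#' Default nucleotide scoring parameters
#'
#' Match +2 / mismatch -3 with gap open 5 / extend 2 and megablast-like
#' Karlin-Altschul parameters (lambda = 0.625, K = 0.41).
#'
#' @param match,mismatch match reward and mismatch penalty.
#' @param gapOpen,gapExtend affine gap penalties (positive).
#' @param lambda,K Karlin-Altschul parameters.
#' @return a [ScoringParams-class] object.
#' @export
nucleotideScoringParams <- function(match = 2, mismatch = -3,
                                    gapOpen = 5, gapExtend = 2,
                                    lambda = 0.625, K = 0.41) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  new("ScoringParams", matrix = mat, gapOpen = gapOpen,
      gapExtend = gapExtend, lambda = lambda, K = K, type = "nucleotide")
}

# map a sequence to 0-based matrix indices, erroring on the first residue
# outside the declared alphabet
.encodeSeq <- function(x, params, what = "sequence") {
  x <- toupper(as.character(x))
  if (nchar(x) == 0L) stop(what, " is empty")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  idx <- match(chars, rownames(params@matrix))
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    stop(sprintf("invalid residue '%s' at position %d of %s",
                 chars[p], p, what))
  }
  idx - 1L
}

#' Karlin-Altschul E-value from a bit score
#'
#' `E = m * n * 2^(-bitScore)`: the expected number of chance local
#' alignments at least as good as the observed one in a search space of
#' `m * n` residue pairs. Strictly decreasing in the bit score and linear
#' in the search space.
#'
#' @param bitScore bit score(s).
#' @param m query length (residues).
#' @param n search-space length: subject length for a single pair, or the
#'   total residue count of the subject set for database-style searches.
#' @return numeric E-value(s).
#' @export
karlinEvalue <- function(bitScore, m, n) {
  stopifnot(m >= 1, n >= 1)
  as.numeric(m) * as.numeric(n) * 2^(-bitScore)
}

.bitScore <- function(rawScore, params) {
  (params@lambda * rawScore - log(params@K)) / log(2)
}

#' Optimal Smith-Waterman local alignment of two sequences
#'
#' Exact affine-gap local alignment (no seeding heuristics) with a total,
#' documented tie-break among co-optimal alignments: earliest query start,
#' then earliest subject start, then earliest ends. Raw scores are converted
#' to bit scores via the Karlin-Altschul parameters in `params` and to
#' E-values over an `m * n` search space.
#'
#' @param query,subject sequences (character, or any object with an
#'   `as.character` method such as `DNAString`/`AAString`).
#' @param params a [ScoringParams-class] object.
#' @param queryId,subjectId ids recorded in the hit table.
#' @param searchSpaceN search-space length for the E-value; defaults to the
#'   subject length (single-pair convention).
#' @param strand strand label stored with the hit (nucleotide searches).
#' @return a hit table (data.frame) with 0 rows (no positive-scoring local
#'   alignment) or 1 row; columns follow BLAST outfmt6 plus
#'   `query_coverage_percent` (aligned query span / query length * 100).
#' @examples
#' p <- nucleotideScoringParams(gapOpen = 5, gapExtend = 2)
#' localAlign("ACGT", "TTACGTTT", p)
#' @export
localAlign <- function(query, subject, params = proteinScoringParams(),
                       queryId = "query", subjectId = "subject",
                       searchSpaceN = NULL, strand = "+") {
  q <- .encodeSeq(query, params, "query")
  s <- .encodeSeq(subject, params, "subject")
  res <- .sw_align(q, s, params@matrix, params@gapOpen, params@gapExtend)
  if (!isTRUE(res$hit)) return(.emptyHits())
  m <- length(q)
  n <- if (is.null(searchSpaceN)) length(s) else searchSpaceN
  bit <- .bitScore(res$score, params)
  data.frame(
    query_id = queryId, subject_id = subjectId,
    identity_percent = 100 * res$identities / res$alignment_length,
    alignment_length = res$alignment_length, identities = res$identities,
    query_start = res$query_start, query_end = res$query_end,
    subject_start = res$subject_start, subject_end = res$subject_end,
    raw_score = res$score, bit_score = bit,
    evalue = karlinEvalue(bit, m, n),
    query_coverage_percent = 100 * (res$query_end - res$query_start + 1) / m,
    strand = strand, stringsAsFactors = FALSE)
}

#' Greedy non-overlapping HSPs of a query against a subject
#'
#' Reports the optimal local alignment, masks its subject interval, and
#' repeats on the unmasked subject segments until the best remaining raw
#' score drops below `minRawScore`. HSPs are therefore non-overlapping on
#' the subject (they may overlap on the query, as for a repeated query).
#'
#' @inheritParams localAlign
#' @param minRawScore stop when the best remaining raw score is below this.
#' @return hit table with one row per HSP, ordered by decreasing raw score.
#' @export
findHsps <- function(query, subject, params = nucleotideScoringParams(),
                     minRawScore = 50, queryId = "query",
                     subjectId = "subject", searchSpaceN = NULL,
                     strand = "+") {
  subject <- toupper(as.character(subject))
  segs <- list(list(offset = 0L, seq = subject))
  segBest <- function(seg) {
    if (nchar(seg$seq) == 0L) return(NULL)
    h <- localAlign(query, seg$seq, params, queryId, subjectId,
                    searchSpaceN = if (is.null(searchSpaceN))
                      nchar(subject) else searchSpaceN,
                    strand = strand)
    if (nrow(h) == 0L) return(NULL)
    h$subject_start <- h$subject_start + seg$offset
    h$subject_end <- h$subject_end + seg$offset
    h
  }
  bests <- lapply(segs, segBest)
  hits <- .emptyHits()
  repeat {
    scores <- vapply(bests, function(h) if (is.null(h)) -Inf else h$raw_score,
                     numeric(1))
    if (!length(scores) || max(scores) < minRawScore) break
    # greedy: best raw score first; ties broken by leftmost subject start
    starts <- vapply(bests, function(h) if (is.null(h)) Inf
                     else h$subject_start, numeric(1))
    k <- order(-scores, starts)[1]
    hit <- bests[[k]]
    hits <- rbind(hits, hit)
    seg <- segs[[k]]
    lcut <- hit$subject_start - 1L - seg$offset   # chars kept on the left
    rfrom <- hit$subject_end + 1L - seg$offset    # first char kept, right
    newsegs <- list()
    if (lcut > 0)
      newsegs <- c(newsegs, list(list(offset = seg$offset,
                                      seq = substr(seg$seq, 1L, lcut))))
    if (rfrom <= nchar(seg$seq))
      newsegs <- c(newsegs, list(list(
        offset = seg$offset + rfrom - 1L,
        seq = substr(seg$seq, rfrom, nchar(seg$seq)))))
    segs <- c(segs[-k], newsegs)
    bests <- c(bests[-k], lapply(newsegs, segBest))
  }
  hits[order(-hits$raw_score, hits$subject_start), , drop = FALSE]
}

#' Write a hit table as BLAST outfmt6-compatible TSV
#'
#' Twelve standard columns plus `query_coverage_percent`.
#'
#' @param hits a hit table from [localAlign()]/[findHsps()].
#' @param path output file.
#' @export
writeHitsTsv <- function(hits, path) {
  cols <- c("query_id", "subject_id", "identity_percent", "alignment_length",
            "identities", "query_start", "query_end", "subject_start",
            "subject_end", "evalue", "bit_score", "raw_score",
            "query_coverage_percent")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
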