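#' Find maximal exact direct repeats shared by two flanks
#'
#' Enumerates every maximal exact common substring of length >=
#' `minCoreLength` between the two sequences, with the 1-based start
#' offsets of both occurrences. "Maximal" means the match cannot be
#' extended on either side; matches are found per diagonal with a
#' run-length scan, so the search is exact and exhaustive.
#'
#' @param leftFlank,rightFlank character (or XString) sequences.
#' @param minCoreLength minimum repeat length (>= 8; attB cores reported
#'   for temperate phages span 13-52 nt, and the default caller uses 12).
#' @return data.frame with columns `core`, `left_start`, `right_start`,
#'   `length`, sorted by decreasing length.
#' @export
findDirectRepeats <- function(leftFlank, rightFlank, minCoreLength = 12) {
  stopifnot(minCoreLength >= 8)
  A <- toupper(as.character(leftFlank))
  B <- toupper(as.character(rightFlank))
  n <- nchar(A); m <- nchar(B)
  if (n == 0L || m == 0L) stop("flanks must be non-empty")
  empty <- data.frame(core = character(), left_start = integer(),
                      right_start = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  k <- as.integer(minCoreLength)
  if (n < k || m < k) return(empty)
  a <- strsplit(A, "", fixed = TRUE)[[1]]
  b <- strsplit(B, "", fixed = TRUE)[[1]]
  # seed: every shared k-mer; extend: each maximal match is seeded exactly
  # once by its left-most k-mer (left-maximality check), then grown right
  kmA <- substring(A, 1:(n - k + 1L), k:n)
  kmB <- substring(B, 1:(m - k + 1L), k:m)
  posB <- split(seq_len(m - k + 1L), kmB)
  shared <- which(kmA %in% names(posB))
  out <- list(); cnt <- 0L
  for (i in shared) {
    for (j in posB[[kmA[i]]]) {
      if (i > 1L && j > 1L && a[i - 1L] == b[j - 1L]) next
      len <- k
      while (i + len <= n && j + len <= m && a[i + len] == b[j + len])
        len <- len + 1L
      # skip seeds interior to an already-left-maximal match: only the
      # left-maximal seed of each run survives the check above, but a run
      # of length L yields L-k+1 seeds; interior ones fail left-maximality
      cnt <- cnt + 1L
      out[[cnt]] <- c(i, j, len)
    }
  }
  if (!cnt) return(empty)
  mat <- do.call(rbind, out)
  res <- data.frame(core = substring(A, mat[, 1], mat[, 1] + mat[, 3] - 1L),
                    left_start = mat[, 1], right_start = mat[, 2],
                    length = mat[, 3], stringsAsFactors = FALSE)
  res <- unique(res)
  res[order(-res$length, res$left_start, res$right_start), , drop = FALSE]
}

#' Does an att candidate reconstitute an intact tRNA gene?
#'
#' TRUE iff one att copy overlaps or immediately abuts the 3' terminus of
#' the tRNA gene so that excising `[attL start, attR start)` restores a
#' contiguous intact gene: for a plus-strand tRNA the left (upstream) copy
#' must reach the gene's 3' end; for a minus-strand tRNA the right copy
#' must reach the gene's genomic-left (3') end.
#'
#' @param attL,attR `IRanges` (length 1) of the two repeat copies.
#' @param trnaFeature a length-1 `GRanges` with strand.
#' @return logical.
#' @export
checkTrnaReconstitution <- function(attL, attR, trnaFeature) {
  ts <- GenomicRanges::start(trnaFeature)
  te <- GenomicRanges::end(trnaFeature)
  if (as.character(GenomicRanges::strand(trnaFeature)) == "-") {
    # 3' terminus is the genomic start; the downstream (right) copy must
    # carry it so that excision leaves the gene intact
    (IRanges::start(attR) <= ts && IRanges::end(attR) >= ts) ||
      IRanges::end(attR) == ts - 1L
  } else {
    (IRanges::start(attL) <= te && IRanges::end(attL) >= te) ||
      IRanges::start(attL) == te + 1L
  }
}

# host genes are features not generated as part of a phage cassette
.isHostFeature <- function(features) {
  mc <- GenomicRanges::mcols(features)
  if (!"module_category" %in% names(mc)) return(rep(TRUE, length(features)))
  is.na(mc$module_category) | mc$module_category %in% c("other", "")
}

#' Classify an integration site
#'
#' `tRNA` when the candidate reconstitutes a tRNA 3' end;
#' `gene_disruption` when the insertion point lies inside a host CDS;
#' `intergenic` otherwise.
#'
#' @param attL,attR `IRanges` of the repeat copies (for repeat-less
#'   insertions pass the zero-width insertion point as both).
#' @param features lysogen `GRanges` annotation.
#' @return list with `siteClass` and `targetFeature` (feature ID or `NA`).
#' @export
classifySite <- function(attL, attR, features) {
  mc <- GenomicRanges::mcols(features)
  host <- .isHostFeature(features)
  trnas <- features[host & mc$type == "tRNA"]
  for (i in seq_along(trnas)) {
    if (checkTrnaReconstitution(attL, attR, trnas[i]))
      return(list(siteClass = "tRNA",
                  targetFeature = GenomicRanges::mcols(trnas[i])$ID))
  }
  cds <- features[host & mc$type == "CDS"]
  if (length(cds)) {
    ov <- IRanges::findOverlaps(attL, IRanges::ranges(cds))
    if (length(ov))
      return(list(siteClass = "gene_disruption",
                  targetFeature =
                    GenomicRanges::mcols(cds[S4Vectors::subjectHits(ov)[1]])$ID))
  }
  list(siteClass = "intergenic", targetFeature = NA_character_)
}

#' Call the attachment site of an integrated prophage
#'
#' Searches windows of `flankBp` around both ends of a rough prophage
#' interval for direct repeats, ranks candidates by (1) tRNA 3'-end
#' reconstitution, (2) core length, (3) summed proximity of the two copies
#' to the prophage ends, (4) leftmost position (a total, deterministic
#' order), and derives the post-excision attB and the circularised attP
#' junction sequences for the winner.
#'
#' @param sequence lysogen sequence (character or `DNAString`).
#' @param prophageInterval rough 1-based inclusive interval (`IRanges` of
#'   length 1, or numeric `c(start, end)`).
#' @param features lysogen `GRanges` annotation (used for tRNA
#'   reconstitution and site classification).
#' @param flankBp window half-width around each prophage end (default
#'   2000 bp; att cores sit at prophage termini).
#' @param minCoreLength minimum repeat length (default 12, just below the
#'   shortest reported attB core).
#' @param contextBp flanking context included in the derived attB/attP.
#' @return an [AttCall-class], or `NULL` when no repeat passes
#'   `minCoreLength`.
#' @export
callAtt <- function(sequence, prophageInterval, features, flankBp = 2000,
                    minCoreLength = 12, contextBp = 50) {
  seqc <- toupper(as.character(sequence))
  len <- nchar(seqc)
  if (is(prophageInterval, "IRanges")) {
    s <- IRanges::start(prophageInterval)[1]
    e <- IRanges::end(prophageInterval)[1]
  } else {
    s <- prophageInterval[1]; e <- prophageInterval[2]
  }
  if (s < 1 || e > len || s > e) stop("prophage interval outside sequence")
  mid <- floor((s + e) / 2)
  lw1 <- max(1L, s - flankBp); lw2 <- min(mid, s + flankBp)
  rw1 <- max(mid + 1L, e - flankBp); rw2 <- min(len, e + flankBp)
  reps <- findDirectRepeats(substr(seqc, lw1, lw2), substr(seqc, rw1, rw2),
                            minCoreLength)
  if (!nrow(reps)) return(NULL)
  reps$attL_start <- reps$left_start + lw1 - 1L
  reps$attR_start <- reps$right_start + rw1 - 1L
  reps$attL_end <- reps$attL_start + reps$length - 1L
  reps$attR_end <- reps$attR_start + reps$length - 1L
  reps <- reps[reps$attL_end < reps$attR_start, , drop = FALSE]
  if (!nrow(reps)) return(NULL)

  mc <- GenomicRanges::mcols(features)
  trnas <- features[.isHostFeature(features) & mc$type == "tRNA"]
  reps$trna <- vapply(seq_len(nrow(reps)), function(i) {
    al <- IRanges::IRanges(reps$attL_start[i], reps$attL_end[i])
    ar <- IRanges::IRanges(reps$attR_start[i], reps$attR_end[i])
    any(vapply(seq_along(trnas), function(k)
      checkTrnaReconstitution(al, ar, trnas[k]), logical(1)))
  }, logical(1))
  reps$proximity <- abs(reps$attL_start - s) + abs(reps$attR_end - e)
  ord <- order(-reps$trna, -reps$length, reps$proximity,
               reps$attL_start, reps$attR_start)
  best <- reps[ord[1], ]

  attL <- IRanges::IRanges(best$attL_start, best$attL_end)
  attR <- IRanges::IRanges(best$attR_start, best$attR_end)
  cls <- classifySite(attL, attR, features)
  internal <- substr(seqc, best$attL_end + 1L, best$attR_start - 1L)
  attB <- paste0(
    substr(seqc, max(1L, best$attL_start - contextBp), best$attL_start - 1L),
    best$core,
    substr(seqc, best$attR_end + 1L, min(len, best$attR_end + contextBp)))
  attP <- paste0(
    substr(internal, max(1L, nchar(internal) - contextBp + 1L),
           nchar(internal)),
    best$core, substr(internal, 1L, min(contextBp, nchar(internal))))
  new("AttCall", attCore = best$core, attL = attL, attR = attR,
      siteClass = cls$siteClass,
      targetFeature = as.character(cls$targetFeature),
      attB = attB, attP = attP, trnaReconstituted = best$trna)
}

#' Excise a prophage at a called attachment site
#'
#' Removes `[attL start, attR start)` from the lysogen and rejoins, which
#' leaves exactly one copy of the att core at the junction (the restored
#' attB locus).
#'
#' @param sequence lysogen sequence.
#' @param attCall an [AttCall-class].
#' @return the excised (host) sequence as a character string.
#' @export
exciseProphage <- function(sequence, attCall) {
  seqc <- toupper(as.character(sequence))
  l1 <- IRanges::start(attCall@attL)
  r1 <- IRanges::start(attCall@attR)
  paste0(substr(seqc, 1L, l1 - 1L), substr(seqc, r1, nchar(seqc)))
}
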