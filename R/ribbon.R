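.identityBins <- c(0, 85, 95, 99, 100)
.identityBinLabels <- c("<85", "85-95", "95-99", ">=99")

.binIdentity <- function(x, breaks = .identityBins,
                         labels = .identityBinLabels) {
  as.character(cut(x, breaks = breaks, labels = labels,
                   include.lowest = TRUE, right = FALSE))
}

#' All-vs-all nucleotide comparison of (pro)phage genomes
#'
#' For every unordered genome pair, non-overlapping HSPs are collected on
#' both strands (the subject is also searched reverse-complemented, with
#' coordinates mapped back to the plus strand) and filtered at a stringent
#' E-value, the ribbon-plot convention for whole-genome phage comparison.
#' Self-comparisons are excluded.
#'
#' @param genomes named `DNAStringSet` (or named character vector), >= 2
#'   genomes.
#' @param evalueMax E-value threshold (default 1e-100).
#' @param minRawScore minimum HSP raw score; the default 300 makes the
#'   shortest reportable HSP at 100 percent identity about 150 nt under
#'   the +2/-3 scoring.
#' @param params nucleotide [ScoringParams-class].
#' @return data.frame of ribbon hits: `genome_a`, `genome_b`, `start_a`,
#'   `end_a`, `start_b`, `end_b`, `strand`, `identity_percent`,
#'   `bit_score`, `evalue`, `identity_bin`.
#' @export
allVsAllGenomes <- function(genomes, evalueMax = 1e-100, minRawScore = 300,
                            params = nucleotideScoringParams()) {
  g <- as.character(genomes)
  names(g) <- names(genomes)
  stopifnot(length(g) >= 2, !is.null(names(g)))
  rows <- list(); k <- 0L
  for (i in seq_len(length(g) - 1)) for (j in seq(i + 1, length(g))) {
    lenB <- nchar(g[[j]])
    for (str in c("+", "-")) {
      subj <- if (str == "+") g[[j]] else
        as.character(Biostrings::reverseComplement(DNAString(g[[j]])))
      h <- findHsps(g[[i]], subj, params, minRawScore,
                    queryId = names(g)[i], subjectId = names(g)[j],
                    strand = str)
      if (!nrow(h)) next
      if (str == "-") {
        s2 <- lenB - h$subject_end + 1L
        e2 <- lenB - h$subject_start + 1L
        h$subject_start <- s2; h$subject_end <- e2
      }
      h <- h[h$evalue <= evalueMax, , drop = FALSE]
      if (!nrow(h)) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        genome_a = names(g)[i], genome_b = names(g)[j],
        start_a = h$query_start, end_a = h$query_end,
        start_b = h$subject_start, end_b = h$subject_end,
        strand = h$strand, identity_percent = h$identity_percent,
        bit_score = h$bit_score, evalue = h$evalue,
        identity_bin = .binIdentity(h$identity_percent),
        stringsAsFactors = FALSE)
    }
  }
  if (!k) return(data.frame(
    genome_a = character(), genome_b = character(), start_a = integer(),
    end_a = integer(), start_b = integer(), end_b = integer(),
    strand = character(), identity_percent = numeric(),
    bit_score = numeric(), evalue = numeric(), identity_bin = character(),
    stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Classify genome relationships from ribbon hits
#'
#' `unique`: no hits at all against any other genome. `near_identical`:
#' some partner's high-identity HSPs (>= `nearIdentity` percent) cover at
#' least `nearMutualCoverage` percent of both genomes. `local_similarity`
#' otherwise. Near-identity is symmetric: if A lists B as a partner, B
#' lists A.
#'
#' @param genomes named `DNAStringSet`/character vector used for lengths.
#' @param hits ribbon hits from [allVsAllGenomes()].
#' @param nearIdentity identity floor for the near-identical class
#'   (default 99 percent, i.e. "99-100 percent identity" pairs).
#' @param nearMutualCoverage minimum mutual genome coverage (default 95
#'   percent).
#' @return data.frame: `genome`, `class`, `partners`
#'   (semicolon-separated).
#' @export
classifyRelationships <- function(genomes, hits, nearIdentity = 99,
                                  nearMutualCoverage = 95) {
  g <- as.character(genomes)
  names(g) <- names(genomes)
  lens <- nchar(g)
  res <- lapply(names(g), function(nm) {
    mine <- hits[hits$genome_a == nm | hits$genome_b == nm, , drop = FALSE]
    if (!nrow(mine))
      return(data.frame(genome = nm, class = "unique", partners = "",
                        stringsAsFactors = FALSE))
    partners <- setdiff(unique(c(mine$genome_a, mine$genome_b)), nm)
    near <- vapply(partners, function(p) {
      ph <- mine[(mine$genome_a == p | mine$genome_b == p) &
                   mine$identity_percent >= nearIdentity, , drop = FALSE]
      if (!nrow(ph)) return(FALSE)
      sideMe <- ifelse(ph$genome_a == nm, "a", "b")
      rMe <- c(IRanges::IRanges(ph$start_a[sideMe == "a"],
                                ph$end_a[sideMe == "a"]),
               IRanges::IRanges(ph$start_b[sideMe == "b"],
                                ph$end_b[sideMe == "b"]))
      rP <- c(IRanges::IRanges(ph$start_b[sideMe == "a"],
                               ph$end_b[sideMe == "a"]),
              IRanges::IRanges(ph$start_a[sideMe == "b"],
                               ph$end_a[sideMe == "b"]))
      covMe <- 100 * sum(IRanges::width(IRanges::reduce(rMe))) / lens[[nm]]
      covP <- 100 * sum(IRanges::width(IRanges::reduce(rP))) / lens[[p]]
      covMe >= nearMutualCoverage && covP >= nearMutualCoverage
    }, logical(1))
    if (any(near))
      data.frame(genome = nm, class = "near_identical",
                 partners = paste(partners[near], collapse = ";"),
                 stringsAsFactors = FALSE)
    else
      data.frame(genome = nm, class = "local_similarity",
                 partners = paste(partners, collapse = ";"),
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-window hit-frequency profile of one genome
#'
#' Counts, for each fixed-width window along the genome, the HSPs whose
#' interval on that genome overlaps the window (the histogram ring of a
#' circular ribbon plot).
#'
#' @param genomeName genome id as used in the hits.
#' @param genomeLength genome length in bp.
#' @param hits ribbon hits from [allVsAllGenomes()].
#' @param binSize window width in bp (>= 100).
#' @return data.frame: `start`, `end`, `count`.
#' @export
hitFrequencyProfile <- function(genomeName, genomeLength, hits,
                                binSize = 1000) {
  stopifnot(binSize >= 100)
  starts <- seq(1L, genomeLength, by = binSize)
  wins <- IRanges::IRanges(starts, width = pmin(binSize,
                                                genomeLength - starts + 1L))
  mine <- hits[hits$genome_a == genomeName | hits$genome_b == genomeName, ,
               drop = FALSE]
  if (nrow(mine)) {
    onA <- mine$genome_a == genomeName
    iv <- IRanges::IRanges(
      ifelse(onA, mine$start_a, mine$start_b),
      ifelse(onA, mine$end_a, mine$end_b))
    counts <- IRanges::countOverlaps(wins, iv)
  } else {
    counts <- integer(length(wins))
  }
  data.frame(start = IRanges::start(wins), end = IRanges::end(wins),
             count = as.integer(counts))
}
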