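.requiredModules <- c("integration", "lysogeny_switch", "packaging",
                      "head_tail", "lysis")

.moduleVocabulary <- c(.requiredModules, "replication", "mtase", "parB_like",
                       "terminase_large", "other")

#' Keyword mapping from product text to module category
#'
#' A convenience table for annotations that carry free-text products but no
#' `module_category` attribute; overridable and deliberately conservative.
#'
#' @return data.frame with `pattern` (regex, case-insensitive) and
#'   `category`.
#' @export
productCategoryMap <- function() {
  data.frame(
    pattern = c("integrase|recombinase|transposase", "terminase",
                "endolysin|holin|lysin|amidase|muramidase",
                "capsid|tail|portal|head", "\\bCI\\b|\\bCro\\b|XRE",
                "replication|primase|helicase", "methyltransferase|MTase",
                "ParB"),
    category = c("integration", "packaging", "lysis", "head_tail",
                 "lysogeny_switch", "replication", "mtase", "parB_like"),
    stringsAsFactors = FALSE)
}

#' Assign module categories from product text
#'
#' Fills missing/`other` `module_category` values of a feature set by
#' matching product descriptions against [productCategoryMap()].
#'
#' @param features a `GRanges` with a `product` column.
#' @param map keyword map (defaults to [productCategoryMap()]).
#' @return the features with `module_category` filled in.
#' @export
categorizeByProduct <- function(features, map = productCategoryMap()) {
  mc <- GenomicRanges::mcols(features)
  cat <- if ("module_category" %in% names(mc)) mc$module_category
         else rep(NA_character_, length(features))
  todo <- is.na(cat) | cat %in% c("", "other")
  for (i in seq_len(nrow(map))) {
    hit <- todo & grepl(map$pattern[i], mc$product, ignore.case = TRUE)
    cat[hit] <- map$category[i]
    todo <- todo & !hit
  }
  cat[is.na(cat)] <- "other"
  GenomicRanges::mcols(features)$module_category <- cat
  features
}

#' Assess prophage completeness from module-labelled annotation
#'
#' A candidate prophage region is complete when it carries at least one
#' gene from each of the five required modules: integration, lysis/lysogeny
#' switch, DNA packaging, head-tail assembly and lysis.
#'
#' @param features `GRanges` (or data.frame) of genes in the region with a
#'   `module_category` column.
#' @return a [CompletenessReport-class].
#' @export
assessCompleteness <- function(features) {
  cats <- if (is(features, "GRanges"))
    GenomicRanges::mcols(features)$module_category
  else features$module_category
  present <- intersect(.requiredModules, unique(as.character(cats)))
  missing <- setdiff(.requiredModules, present)
  new("CompletenessReport", presentModules = present,
      missingModules = missing, complete = length(missing) == 0L)
}

#' GC content of a sequence, in percent
#'
#' `100 * (G + C) / (A + C + G + T)`; IUPAC ambiguity codes are excluded
#' from numerator and denominator alike.
#'
#' @param sequence character or `DNAString`.
#' @return percent GC.
#' @export
gcContent <- function(sequence) {
  seqc <- toupper(as.character(sequence))
  if (nchar(seqc) == 0L) stop("sequence is empty")
  counts <- table(strsplit(seqc, "", fixed = TRUE)[[1]])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  if (acgt == 0L) stop("sequence contains no unambiguous bases")
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  100 * gc / acgt
}

#' Refine prophage boundaries by GC contrast
#'
#' Estimates the host background GC from the sequence outside the rough
#' interval and the prophage GC from the interval's central half, then
#' re-places each boundary by a two-segment changepoint fit: the boundary
#' position that best splits the local sequence into a background-like and
#' a prophage-like segment (a base-level CUSUM statistic, robust to the
#' window-scale GC fluctuation inherent in real genomes). The contrast
#' gate is applied afterwards, on the refined interval: when its GC
#' differs from the background by less than `minContrast` percentage
#' points the rough interval is returned unchanged with
#' `refined = FALSE`. A sliding-window GC profile is returned for plotting
#' either way.
#'
#' @param sequence replicon sequence.
#' @param roughInterval numeric `c(start, end)` or length-1 `IRanges`.
#' @param window profile window width in bp (default 500); also sets the
#'   boundary search range (4 windows around each rough end).
#' @param step profile window step in bp (default 100).
#' @param minContrast minimum |prophage GC - background GC| in percentage
#'   points required to attempt refinement (default 2.5; must be > 0).
#' @param anchorPenalty per-base penalty (in units of `minContrast / 100`)
#'   on moving a boundary away from its rough position; the default 2
#'   makes the fit conservative: a boundary only moves when the
#'   compositional evidence along the way is decisive, which suppresses
#'   the long random excursions a plain changepoint fit is prone to at
#'   weak contrast.
#' @return list with `interval` (`c(start, end)`), `refined` (logical),
#'   `backgroundGc`, `prophageGc`, and `profile` (data.frame: start, end,
#'   gc, qualifying).
#' @export
refineBoundariesByGc <- function(sequence, roughInterval, window = 500,
                                 step = 100, minContrast = 2.5,
                                 anchorPenalty = 2) {
  if (minContrast <= 0) stop("minContrast must be > 0")
  seqc <- toupper(as.character(sequence))
  len <- nchar(seqc)
  if (is(roughInterval, "IRanges"))
    roughInterval <- c(IRanges::start(roughInterval)[1],
                       IRanges::end(roughInterval)[1])
  s <- as.integer(roughInterval[1]); e <- as.integer(roughInterval[2])
  if (s < 1 || e > len || s > e) stop("rough interval outside sequence")
  if (window > e - s + 1) stop("window larger than the rough interval")

  flank <- paste0(substr(seqc, 1L, s - 1L), substr(seqc, e + 1L, len))
  if (nchar(flank) == 0L) stop("no flanking sequence to estimate background")
  bg <- gcContent(flank)
  q <- floor((e - s + 1) / 4)
  pro <- gcContent(substr(seqc, s + q, e - q))

  starts <- seq(1L, len - window + 1L, by = step)
  gc <- vapply(starts, function(w)
    gcContent(substr(seqc, w, w + window - 1L)), numeric(1))
  profile <- data.frame(start = starts, end = starts + window - 1L,
                        gc = gc, qualifying = abs(gc - bg) >= minContrast)

  isGc <- as.integer(strsplit(seqc, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  thr <- (bg + pro) / 200      # midpoint of the two compositions, as a rate
  sgn <- sign(pro - bg)
  lambda <- anchorPenalty * minContrast / 100
  mid <- floor((s + e) / 2)
  reach <- 4L * window
  # left boundary b maximises the prophage-likeness of [b, mid], less the
  # anchor penalty for straying from the rough boundary
  lo <- max(1L, s - reach); hi <- min(mid, s + reach)
  seg <- isGc[lo:mid]
  score <- rev(cumsum(rev(sgn * (seg - thr))))   # score[k] = sum from k to end
  pos <- lo:hi
  newS <- pos[which.max(score[seq_len(hi - lo + 1L)] - lambda * abs(pos - s))]
  # right boundary b maximises the prophage-likeness of [mid, b]
  lo2 <- max(mid, e - reach); hi2 <- min(len, e + reach)
  seg2 <- isGc[mid:hi2]
  score2 <- cumsum(sgn * (seg2 - thr))           # score2[k] = sum mid..mid+k-1
  offs <- (lo2 - mid + 1L):(hi2 - mid + 1L)
  pos2 <- mid + offs - 1L
  newE <- pos2[which.max(score2[offs] - lambda * abs(pos2 - e))]
  # the contrast gate is applied to the refined interval, whose GC estimate
  # is not contaminated by host sequence inside an imprecise rough interval
  proFinal <- gcContent(substr(seqc, newS, newE))
  if (abs(proFinal - bg) < minContrast)
    return(list(interval = c(s, e), refined = FALSE, backgroundGc = bg,
                prophageGc = proFinal, profile = profile))
  list(interval = c(newS, newE), refined = TRUE, backgroundGc = bg,
       prophageGc = proFinal, profile = profile)
}

#' Classify the locus context of a phage methyltransferase gene
#'
#' Phage DNA methyltransferase (MTase) genes cluster at characteristic
#' genomic locations. `ParB_Tls`: the MTase lies between a ParB-like gene
#' (upstream) and the terminase large subunit gene, i.e. the conserved
#' ParB-Tls locus ahead of the packaging module. Otherwise the nearest
#' labelled module within `window` intervening genes decides, in priority
#' order: downstream of the integrase, upstream of the integrase,
#' downstream of the lysis module, near the replication module; `other`
#' when no module is close. Gene order is genomic coordinate order.
#'
#' @param mtaseId feature ID of the MTase gene.
#' @param features `GRanges` with `module_category` labels.
#' @param window maximum number of intervening genes (default 2).
#' @param parbWindow maximum ParB-to-terminase gene span for the ParB-Tls
#'   call (default 10); the two genes must share a strand.
#' @return one of `"ParB_Tls"`, `"downstream_integrase"`,
#'   `"upstream_integrase"`, `"downstream_lysis"`, `"near_replication"`,
#'   `"other"`.
#' @export
classifyMtaseLocus <- function(mtaseId, features, window = 2,
                               parbWindow = 10) {
  ord <- order(GenomicRanges::start(features))
  feats <- features[ord]
  mc <- GenomicRanges::mcols(feats)
  idx <- which(mc$ID == mtaseId)
  if (!length(idx)) stop("MTase feature not found: ", mtaseId)
  idx <- idx[1]
  cat <- mc$module_category
  strands <- as.character(GenomicRanges::strand(feats))

  parb <- which(cat == "parB_like" & seq_along(cat) < idx)
  tls <- which(cat == "terminase_large" & seq_along(cat) > idx)
  for (i in parb) for (j in tls) {
    if (j - i <= parbWindow && strands[i] == strands[j])
      return("ParB_Tls")
  }

  near <- function(cats, side) {
    cand <- which(cat %in% cats)
    if (side == "up") cand <- cand[cand < idx & idx - cand <= window + 1L]
    else if (side == "down")
      cand <- cand[cand > idx & cand - idx <= window + 1L]
    else cand <- cand[abs(cand - idx) <= window + 1L & cand != idx]
    length(cand) > 0L
  }
  if (near("integration", "up")) return("downstream_integrase")
  if (near("integration", "down")) return("upstream_integrase")
  if (near("lysis", "up")) return("downstream_lysis")
  if (near("replication", "both")) return("near_replication")
  "other"
}
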