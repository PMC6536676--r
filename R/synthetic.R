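#' @importFrom Biostrings DNAString DNAStringSet AAStringSet writeXStringSet
#'   reverseComplement
#' @importFrom GenomicRanges GRanges mcols mcols<- start end strand
#' @importFrom IRanges IRanges
NULL

.DNA <- c("A", "C", "G", "T")
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.randomDna <- function(n, gcPercent) {
  g <- gcPercent / 100
  paste(sample(.DNA, n, replace = TRUE,
               prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)),
        collapse = "")
}

.randomProtein <- function(n) {
  paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

#' Specification of a synthetic host replicon
#'
#' @param length replicon length in bp.
#' @param gcTarget target GC content in percent (0 < gcTarget < 100 for a
#'   mixed-composition genome; 0 and 100 give all-AT / all-GC sequences).
#' @param trnaGenes data.frame with columns `position` (start), `length`,
#'   `name`, and optionally `strand` (`"+"`/`"-"`, default `"+"`); the
#'   planted tRNA genes.
#' @param cdsDensity protein-coding genes per kb placed in the remaining
#'   space (default 0.8, a typical bacterial gene density).
#' @return a list spec consumed by [generateHostGenome()].
#' @export
hostGenomeSpec <- function(length = 50000, gcTarget = 65,
                           trnaGenes = data.frame(
                             position = round(length / 2), length = 76,
                             name = "tRNA-Met(CAT)", strand = "+",
                             stringsAsFactors = FALSE),
                           cdsDensity = 0.8) {
  stopifnot(length >= 1, gcTarget >= 0, gcTarget <= 100)
  if (!is.null(trnaGenes) && nrow(trnaGenes)) {
    if (is.null(trnaGenes$strand)) trnaGenes$strand <- "+"
    ends <- trnaGenes$position + trnaGenes$length - 1
    if (any(trnaGenes$position < 1) || any(ends > length))
      stop("tRNA gene outside [1, length]")
  }
  list(length = as.integer(length), gcTarget = gcTarget,
       trnaGenes = trnaGenes, cdsDensity = cdsDensity)
}

#' Generate a synthetic host replicon with annotated features
#'
#' Draws an i.i.d. sequence with per-base probabilities set from the GC
#' target (no repeat structure is injected, which keeps downstream
#' direct-repeat searches clean), plants the specified tRNA genes and fills
#' the remaining space with non-overlapping CDS features at the requested
#' density. Deterministic for a fixed seed.
#'
#' @param spec a spec from [hostGenomeSpec()].
#' @param seed integer seed (required; all generators are reproducible).
#' @return list with `sequence` (a `DNAString`) and `features` (a
#'   `GRanges` with `type`, `ID`, `product`, `module_category` columns).
#' @export
generateHostGenome <- function(spec = hostGenomeSpec(), seed) {
  stopifnot(is.numeric(seed))
  withr::with_seed(as.integer(seed), {
    seqc <- .randomDna(spec$length, spec$gcTarget)
    feats <- list()
    occupied <- IRanges()
    tg <- spec$trnaGenes
    if (!is.null(tg) && nrow(tg)) {
      r <- IRanges(start = tg$position, width = tg$length)
      occupied <- c(occupied, r)
      feats$trna <- GRanges("host", r, strand = tg$strand,
                            type = "tRNA", ID = tg$name, product = tg$name,
                            module_category = "other")
    }
    nCds <- max(0L, round(spec$cdsDensity * spec$length / 1000))
    if (nCds > 0) {
      starts <- integer(); widths <- integer()
      pos <- 1L; i <- 0L
      gap <- max(50L, floor(spec$length / nCds * 0.2))
      while (i < nCds && pos < spec$length - 300L) {
        w <- sample(300:1200, 1)
        cand <- IRanges(pos, width = min(w, spec$length - pos + 1L))
        if (length(occupied) == 0L ||
            sum(IRanges::countOverlaps(cand, occupied)) == 0L) {
          starts <- c(starts, pos); widths <- c(widths, IRanges::width(cand))
          pos <- pos + IRanges::width(cand) + gap
          i <- i + 1L
        } else {
          ov <- occupied[IRanges::countOverlaps(occupied, cand) > 0]
          pos <- max(end(ov)) + gap
        }
      }
      if (length(starts))
        feats$cds <- GRanges("host", IRanges(starts, width = widths),
                             strand = sample(c("+", "-"), length(starts),
                                             replace = TRUE),
                             type = "CDS",
                             ID = sprintf("host_cds_%03d", seq_along(starts)),
                             product = "hypothetical protein",
                             module_category = "other")
    }
    features <- if (length(feats))
      sort(do.call(c, unname(feats)), ignore.strand = TRUE)
    else GRanges()
    list(sequence = DNAString(seqc), features = features)
  })
}

#' Specification of a synthetic temperate-phage cassette
#'
#' The module layout mirrors the modular architecture of temperate phage
#' genomes: ordered functional blocks for integration, the lysis/lysogeny
#' switch, replication, DNA packaging, head-tail assembly and lysis, each
#' with a gene count. Genome-wide defaults (~40 kb, GC distinct from a
#' typical host) follow the size and composition range of sequenced
#' temperate phages of Alphaproteobacteria.
#'
#' @param length cassette length in bp (excluding the att core copies).
#' @param gcTarget cassette GC percent.
#' @param moduleLayout named integer vector, ordered module -> gene count.
#' @param attCoreLength length of the duplicated att core in nt (0 for no
#'   repeat; reported attB cores span 13-52 nt).
#' @param integraseClass `"tyr"`, `"ser"` or `"tnp"`.
#' @return a list spec consumed by [simulateIntegration()].
#' @export
prophageSpec <- function(length = 40000, gcTarget = 60,
                         moduleLayout = c(integration = 1,
                                          lysogeny_switch = 2,
                                          replication = 3, packaging = 2,
                                          head_tail = 8, lysis = 2),
                         attCoreLength = 20, integraseClass = "tyr") {
  stopifnot(length >= 1, attCoreLength >= 0,
            integraseClass %in% c("tyr", "ser", "tnp"))
  required <- c("integration", "lysogeny_switch", "packaging", "head_tail",
                "lysis")
  if (any(duplicated(names(moduleLayout))))
    stop("each module may appear at most once in the layout")
  list(length = as.integer(length), gcTarget = gcTarget,
       moduleLayout = moduleLayout,
       attCoreLength = as.integer(attCoreLength),
       integraseClass = integraseClass, requiredModules = required)
}

# lay the cassette's genes out proportionally over its length
.cassetteFeatures <- function(spec, offset) {
  counts <- spec$moduleLayout
  n <- sum(counts)
  if (n == 0) return(GRanges())
  slot <- floor(spec$length / n)
  w <- max(150L, floor(slot * 0.8))
  starts <- offset + (seq_len(n) - 1L) * slot + 1L
  cat_per_gene <- rep(names(counts), counts)
  GRanges("host", IRanges(starts, width = w), strand = "+",
          type = "CDS",
          ID = sprintf("phage_gene_%03d", seq_len(n)),
          product = cat_per_gene,
          module_category = cat_per_gene)
}

#' Integrate a synthetic prophage into a host genome
#'
#' Emulates site-specific integration: the cassette is inserted at the 3'
#' end of a tRNA gene (duplicating its 3'-terminal `attCoreLength` bases as
#' the attL/attR direct repeats, so that the upstream copy completes an
#' intact tRNA), inside a CDS (gene-disruption case), or at an intergenic
#' position. Returns the lysogen sequence, shifted/augmented features and a
#' machine-readable truth record sufficient to score downstream att and
#' boundary calls.
#'
#' @param host list from [generateHostGenome()].
#' @param prophage a spec from [prophageSpec()].
#' @param targetFeature ID of a tRNA or CDS feature in `host$features`, or
#'   `"intergenic"`.
#' @param seed integer seed.
#' @return list with `sequence` (lysogen `DNAString`), `features`
#'   (`GRanges`; host features shifted, cassette genes added, disrupted CDS
#'   flagged) and `truth` (list: `prophage_interval`, `attL`, `attR`,
#'   `att_core`, `target_feature`, `site_class`, `cassette_interval`).
#' @export
simulateIntegration <- function(host, prophage, targetFeature, seed) {
  stopifnot(is.numeric(seed))
  withr::with_seed(as.integer(seed), {
    hostSeq <- as.character(host$sequence)
    hostLen <- nchar(hostSeq)
    feats <- host$features
    L <- prophage$attCoreLength
    cassette <- .randomDna(prophage$length, prophage$gcTarget)
    clen <- prophage$length

    if (identical(targetFeature, "intergenic")) {
      gaps <- IRanges::gaps(IRanges::reduce(IRanges::ranges(feats)),
                            start = 1L, end = hostLen)
      gaps <- gaps[IRanges::width(gaps) > 2L * L + 10L]
      if (!length(gaps)) stop("no intergenic gap can host the insertion")
      g <- gaps[which.max(IRanges::width(gaps))]
      p <- start(g) + floor(IRanges::width(g) / 2)
      siteClass <- "intergenic"; targetId <- NA_character_
      strandPlus <- TRUE
    } else {
      hit <- which(mcols(feats)$ID == targetFeature)
      if (!length(hit)) stop("target feature not found: ", targetFeature)
      f <- feats[hit[1]]
      if (IRanges::width(f) < L)
        stop("target feature too short for the att core length")
      if (mcols(f)$type == "tRNA") {
        siteClass <- "tRNA"
        strandPlus <- as.character(strand(f)) != "-"
        p <- if (strandPlus) end(f) else start(f) - 1L  # insert after p
      } else {
        siteClass <- "gene_disruption"
        strandPlus <- TRUE
        p <- start(f) + floor(IRanges::width(f) / 2)
      }
      targetId <- mcols(f)$ID
    }

    if (L > 0 && (p - L + 1 < 1) && strandPlus)
      stop("target feature too short for the att core length")

    # keep the planted core exactly maximal: the cassette must not extend
    # the repeat by chance agreement with the host bases adjoining the core
    fixEnds <- function(cass, beforeCore, afterCore) {
      if (L == 0L) return(cass)
      if (nzchar(afterCore) && substr(cass, 1L, 1L) == afterCore)
        substr(cass, 1L, 1L) <- sample(setdiff(.DNA, afterCore), 1)
      if (nzchar(beforeCore) && substr(cass, clen, clen) == beforeCore)
        substr(cass, clen, clen) <- sample(setdiff(.DNA, beforeCore), 1)
      cass
    }

    if (strandPlus || identical(targetFeature, "intergenic") ||
        siteClass != "tRNA") {
      # core = the L bases ending at p; insert cassette + duplicate after p
      core <- if (L > 0) substr(hostSeq, p - L + 1L, p) else ""
      cassette <- fixEnds(cassette,
                          if (p - L >= 1L) substr(hostSeq, p - L, p - L)
                          else "",
                          substr(hostSeq, p + 1L, p + 1L))
      lysogen <- paste0(substr(hostSeq, 1L, p), cassette, core,
                        substr(hostSeq, p + 1L, hostLen))
      attL <- IRanges(p - L + 1L, width = L)
      attR <- IRanges(p + clen + 1L, width = L)
      insAt <- p
    } else {
      # minus-strand tRNA: 3' terminus is the genomic start; the duplicate
      # goes to the genomic left of the (shifted) gene
      a <- p + 1L  # original gene start
      core <- substr(hostSeq, a, a + L - 1L)
      cassette <- fixEnds(cassette,
                          if (a > 1L) substr(hostSeq, a - 1L, a - 1L) else "",
                          substr(hostSeq, a + L, a + L))
      lysogen <- paste0(substr(hostSeq, 1L, a - 1L), core, cassette,
                        substr(hostSeq, a, hostLen))
      attL <- IRanges(a, width = L)
      attR <- IRanges(a + L + clen, width = L)
      insAt <- a - 1L
    }

    shift <- clen + L
    newFeats <- feats
    mv <- start(newFeats) > insAt
    # features downstream of the insertion point shift right
    newFeats[mv] <- IRanges::shift(newFeats[mv], shift)
    disrupted <- rep(FALSE, length(newFeats))
    if (siteClass == "gene_disruption")
      disrupted[mcols(newFeats)$ID == targetId] <- TRUE
    mcols(newFeats)$disrupted <- disrupted
    cassFeats <- .cassetteFeatures(prophage, insAt + if (strandPlus ||
        siteClass != "tRNA") 0L else L)
    if (length(cassFeats)) mcols(cassFeats)$disrupted <- FALSE
    allFeats <- sort(c(newFeats, cassFeats), ignore.strand = TRUE)

    if (L > 0) {
      prophageInt <- IRanges(start(attL), end(attR))
    } else {
      prophageInt <- IRanges(insAt + 1L, insAt + clen)
    }
    list(sequence = DNAString(lysogen), features = allFeats,
         truth = list(prophage_interval = prophageInt,
                      attL = attL, attR = attR, att_core = core,
                      target_feature = targetId, site_class = siteClass,
                      cassette_interval = IRanges(
                        insAt + 1L + if (strandPlus || siteClass != "tRNA")
                          0L else L, width = clen)))
  })
}

#' Mutate a sequence to a target percent identity
#'
#' Point substitutions only (length preserved): `round((100 - target)/100
#' * L)` positions are chosen without replacement and each is replaced by a
#' different symbol drawn uniformly from the rest of the alphabet, so the
#' realised ungapped identity equals the target up to rounding.
#'
#' @param sequence character (or XString) sequence.
#' @param targetIdentity percent identity in `[0, 100]`.
#' @param seed integer seed.
#' @param alphabet symbol set; defaults to the 20 standard amino acids, or
#'   ACGT when the sequence contains only nucleotide symbols.
#' @return mutated character sequence.
#' @export
mutateToIdentity <- function(sequence, targetIdentity, seed,
                             alphabet = NULL) {
  stopifnot(targetIdentity >= 0, targetIdentity <= 100, is.numeric(seed))
  x <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
  if (is.null(alphabet))
    alphabet <- if (all(x %in% .DNA)) .DNA else .AA20
  k <- round((100 - targetIdentity) / 100 * length(x))
  if (k == 0) return(paste(x, collapse = ""))
  withr::with_seed(as.integer(seed), {
    pos <- sample(length(x), k)
    for (i in pos) {
      choices <- setdiff(alphabet, x[i])
      x[i] <- sample(choices, 1)
    }
  })
  paste(x, collapse = "")
}

#' Generate phage proteomes with planted homolog clusters
#'
#' Phage pair (i, j) shares exactly `sharedMatrix[i, j]` planted homolog
#' pairs: each pair is one random protein placed in proteome i and a copy
#' mutated to the requested identity placed in proteome j. All remaining
#' proteins are mutually unrelated random sequences over a uniform 20-letter
#' background, so chance similarity at gene-sharing thresholds is
#' negligible. The truth table records every planted pair.
#'
#' @param nPhages number of proteomes.
#' @param sharedMatrix symmetric non-negative integer matrix of planted
#'   shared-protein counts (diagonal ignored).
#' @param identityLevels percent identity of planted pairs: a scalar or a
#'   matrix conformable with `sharedMatrix` (default 100).
#' @param seed integer seed.
#' @param nUnique unrelated proteins per phage (default 8).
#' @param proteinLength length of generated proteins (default 250 aa).
#' @return list with `proteomes` (named list of `AAStringSet`) and `truth`
#'   (data.frame: phage_i, phage_j, protein_i, protein_j, identity).
#' @export
generateProteomeClusters <- function(nPhages, sharedMatrix,
                                     identityLevels = 100, seed,
                                     nUnique = 8, proteinLength = 250) {
  stopifnot(is.matrix(sharedMatrix),
            nrow(sharedMatrix) == nPhages, ncol(sharedMatrix) == nPhages,
            all(sharedMatrix >= 0), isSymmetric(unname(sharedMatrix)))
  if (!is.matrix(identityLevels))
    identityLevels <- matrix(identityLevels, nPhages, nPhages)
  phages <- sprintf("phage%02d", seq_len(nPhages))
  withr::with_seed(as.integer(seed), {
    prot <- lapply(phages, function(p) character())
    names(prot) <- phages
    truth <- list()
    fam <- 0L
    for (i in seq_len(nPhages - 1)) for (j in seq(i + 1, nPhages)) {
      s <- sharedMatrix[i, j]
      if (s == 0) next
      for (k in seq_len(s)) {
        fam <- fam + 1L
        base <- .randomProtein(proteinLength)
        idA <- sprintf("%s|shared_%03d", phages[i], fam)
        idB <- sprintf("%s|shared_%03d", phages[j], fam)
        mutSeed <- sample.int(.Machine$integer.max, 1)
        mut <- mutateToIdentity(base, identityLevels[i, j], mutSeed, .AA20)
        prot[[i]][idA] <- base
        prot[[j]][idB] <- mut
        truth[[fam]] <- data.frame(
          phage_i = phages[i], phage_j = phages[j],
          protein_i = idA, protein_j = idB,
          identity = identityLevels[i, j], stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nPhages)) {
      u <- vapply(seq_len(nUnique), function(k) .randomProtein(proteinLength),
                  character(1))
      names(u) <- sprintf("%s|unique_%03d", phages[i], seq_len(nUnique))
      prot[[i]] <- c(prot[[i]], u)
    }
    list(proteomes = lapply(prot, AAStringSet),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(phage_i = character(), phage_j = character(),
                      protein_i = character(), protein_j = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  })
}

#' Write features as GFF3
#'
#' Thin wrapper over `rtracklayer::export` keeping the `module_category`
#' and `product` attributes.
#'
#' @param features a `GRanges` with metadata columns.
#' @param path output GFF3 path.
#' @export
writeFeaturesGff3 <- function(features, path) {
  mc <- GenomicRanges::mcols(features)
  if (!"phase" %in% names(mc) && "type" %in% names(mc)) {
    # GFF3 requires a phase on CDS rows; generated genes are frame 0
    GenomicRanges::mcols(features)$phase <-
      ifelse(mc$type == "CDS", 0L, NA_integer_)
  }
  rtracklayer::export(features, path, format = "gff3")
  invisible(path)
}

#' Read features from GFF3
#'
#' @param path GFF3 file.
#' @return a `GRanges` with the attribute columns restored.
#' @export
readFeaturesGff3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}
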